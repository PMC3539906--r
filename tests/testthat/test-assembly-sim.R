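test_that("digestion splits at every site with the enzyme's cut geometry", {
  es <- fix_es()
  frags <- digest("AAGGATCCTT", "BamHI", es)
  expect_equal(vapply(frags, `[[`, "", "top"), c("AAG", "GATCCTT"))
  expect_equal(frags[[1]]$right_overhang, list(seq = "GATC", polarity = "five_prime"))
  expect_equal(frags[[2]]$left_overhang, list(seq = "GATC", polarity = "five_prime"))
  expect_equal(frags[[1]]$left_overhang$polarity, "blunt")

  ## no site: single unchanged fragment
  un <- digest("ACGTACGT", "BamHI", es)
  expect_length(un, 1L)
  expect_equal(un[[1]]$top, "ACGTACGT")

  ## two sites, three fragments
  two <- digest("GGATCCAAGGATCC", "BamHI", es)
  expect_equal(vapply(two, `[[`, "", "top"), c("G", "GATCCAAG", "GATCC"))

  ## 3' cutter: overhang stays on the left fragment's top strand
  sac <- digest("AAGAGCTCTT", "SacI", es)
  expect_equal(vapply(sac, `[[`, "", "top"), c("AAGAGCT", "CTT"))
  expect_equal(sac[[1]]$right_overhang, list(seq = "AGCT", polarity = "three_prime"))
})

test_that("ligation joins compatible ends and rejects mismatches", {
  es <- fix_es()
  ## NcoI end + PciI end reads CCATGT across the junction
  left <- digest("AACCATGG", "NcoI", es)[[1]]
  right <- digest("ACATGTAA", "PciI", es)[[2]]
  joined <- ligate(left, right)
  expect_equal(joined$top, "AACCATGTAA")
  expect_match(joined$top, "CCATGT")

  ## different overhang sequences cannot ligate
  bam <- digest("AAGGATCCTT", "BamHI", es)
  spe <- digest("AAACTAGTTT", "SpeI", es)
  expect_error(ligate(bam[[1]], spe[[2]]), "incompatible ends")
  ## same sequence, different polarity cannot ligate either
  fake <- sim_fragment("CTT", left_overhang = list(seq = "AGCT", polarity = "five_prime"))
  sac <- digest("AAGAGCTCTT", "SacI", es)
  expect_error(ligate(sac[[1]], fake), "incompatible ends")
  expect_equal(ligate(sac[[1]], sac[[2]])$top, "AAGAGCTCTT")
  ## blunt ends are unsupported
  expect_error(ligate(sim_fragment("AAA"), sim_fragment("TTT")),
               "blunt-end ligation")
})

test_that("ligating digestion fragments in order reconstructs the input exactly", {
  es <- fix_es()
  for (seed in 1:10) {
    s <- random_sequence(1200, seed)$residues
    for (nm in c("BamHI", "NcoI", "SacI", "XhoI")) {
      frags <- digest(s, nm, es)
      out <- Reduce(ligate, frags)
      expect_equal(out$top, s, info = paste(nm, "seed", seed))
    }
  }
})

test_that("a two-module hybrid plan reassembles the target byte-for-byte", {
  es <- fix_es()
  s <- planted_background(1400, 700, "CCATGT")
  plan <- plan_partition(s, c(1, 1400), planner_config(), es)
  expect_equal(nrow(plan$modules), 2L)
  res <- simulate_assembly(plan, s)
  expect_identical(res$assembled, s$residues)
  expect_true(res$report$clean)
  ## the completing outer bases were cut away during assembly: with no
  ## terminal enzymes the full product IS the region
  expect_identical(res$assembled_full, s$residues)
})

test_that("a single-module plan returns the region unchanged", {
  es <- fix_es()
  s <- random_sequence(800, 4)
  plan <- plan_partition(s, c(101, 700), planner_config(), es)
  res <- simulate_assembly(plan, s)
  expect_identical(res$assembled, substr(s$residues, 101, 700))
  expect_true(res$report$clean)
})

test_that("re-cutting a restored palindromic junction is detected dynamically and statically", {
  es <- fix_es()
  ## junction 1 BamHI (palindromic), junction 2 BamHI/BclI hybrid: step 2
  ## digests the growing assembly with BamHI and re-cuts junction 1
  s <- planted_background(2000, c(700, 1400), c("GGATCC", "GGATCA"))
  cfg <- planner_config(strict_sequential = FALSE)
  plan <- plan_partition(s, c(1, 2000), cfg, es)
  expect_equal(plan$junctions$left_enzyme, c("BamHI", "BamHI"))
  expect_true(plan$safety$clean)  # lenient static analysis accepts
  res <- simulate_assembly(plan, s)
  expect_identical(res$assembled, s$residues)  # product still correct in silico
  v <- res$report$violations
  expect_equal(nrow(v), 2L)
  ## digesting module 2's amplicon with BamHI also cuts the primer-completed
  ## BamHI site of the downstream hybrid junction, one step early
  expect_equal(v$step, c(1L, 2L))
  expect_equal(v$enzyme, c("BamHI", "BamHI"))
  expect_equal(v$position, c(1400L, 700L))
  expect_equal(v$context, c("module 2", "assembled modules 1..2"))
  ## strict static analysis reports exactly the dynamic violations
  strict_rep <- assembly_safety_check(plan, s, strict = TRUE)
  expect_equal(strict_rep$violations, v)
  ## and the strict planner refuses this layout outright
  expect_error(plan_partition(s, c(1, 2000), planner_config(), es),
               "NoJunctionFound")
})

test_that("dynamic and static safety reports agree across seeded planner output", {
  es <- fix_es()
  for (seed in c(101, 202, 303, 404)) {
    pt <- plannable_target(seed, n_modules = 3)
    plan <- plan_partition(pt$seq, pt$region, planner_config(), es)
    res <- simulate_assembly(plan, pt$seq)
    static <- assembly_safety_check(plan, pt$seq, strict = TRUE)
    expect_equal(res$report$violations, static$violations, info = paste("seed", seed))
    expect_true(res$report$clean)
  }
})
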