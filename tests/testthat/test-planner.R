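test_that("module length uses the 1-based inclusive convention", {
  expect_equal(module_length(8532, 9117), 586L)
  expect_equal(module_length(11205, 12491), 1287L)
  expect_equal(module_length(7, 7), 1L)
  expect_error(module_length(10, 9), "must not exceed")
})

test_that("candidate ranking prefers midpoint proximity, then palindromic", {
  es <- fix_es()
  s <- planted_background(1000, 700, "CCATGT")
  cands <- candidate_junctions(s, c(600, 800), es)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$position, 700L)
  expect_equal(c(cands$left, cands$right), c("NcoI", "PciI"))
  expect_equal(cands$kind, "hybrid")

  s2 <- planted_background(1000, c(690, 700), c("GGATCC", "CCATGT"))
  cands2 <- candidate_junctions(s2, c(600, 800), es)
  expect_equal(cands2$sequence[1], "CCATGT")  # distance 0 beats distance 10
  expect_equal(cands2$sequence[2], "GGATCC")
  ## on equal distance, palindromic outranks hybrid
  s3 <- planted_background(1000, c(694, 706), c("CCATGT", "GGATCC"))
  cands3 <- candidate_junctions(s3, c(600, 800), es)
  expect_equal(cands3$dist, c(6, 6))
  expect_equal(cands3$kind, c("palindromic", "hybrid"))

  expect_equal(nrow(candidate_junctions(strrep("A", 500), c(100, 300), es)), 0L)
  expect_equal(nrow(candidate_junctions(s, c(300, 302), es)), 0L)
})

test_that("methylation avoidance removes Dam-blocked enzymes from candidacy", {
  es <- fix_es()
  s <- planted_background(1000, 700, "GGATCA")  # BamHI+BclI hybrid; BclI is Dam-blocked
  with_avoid <- candidate_junctions(s, c(600, 800), es, avoid_methylation = TRUE)
  without <- candidate_junctions(s, c(600, 800), es)
  expect_equal(nrow(without), 1L)
  expect_equal(nrow(with_avoid), 0L)
})

test_that("partition places planted junctions and verifies its own constraints", {
  es <- fix_es()
  s <- planted_background(3000, c(1000, 2000), c("CCATGT", "GGATCA"))
  plan <- plan_partition(s, c(1, 3000), planner_config(), es)
  expect_equal(nrow(plan$modules), 3L)
  expect_equal(plan$junctions$position, c(1000L, 2000L))
  expect_equal(plan$junctions$kind, c("hybrid", "hybrid"))
  expect_equal(plan$junctions$left_enzyme, c("NcoI", "BamHI"))
  expect_equal(plan$junctions$right_enzyme, c("PciI", "BclI"))
  ## hybrid junctions overlap 4 bp: next start = previous end - 3
  expect_equal(plan$modules$start, c(1L, 1001L, 2001L))
  expect_equal(plan$modules$end, c(1004L, 2004L, 3000L))
  expect_true(plan$safety$clean)
  ## tiling identity: module lengths minus junction overlaps = region length
  expect_equal(sum(plan$modules$length) - sum(plan$junctions$overlap_len), 3000L)
  ## constraint (a) re-verified post hoc: flanking enzymes absent inside modules
  for (k in seq_len(nrow(plan$junctions))) {
    L <- enzyme_lookup(es, plan$junctions$left_enzyme[k])
    m <- plan$modules[k, ]
    inside <- scan_sites(substr(s$residues, m$start, m$end), es)
    expect_false(L$site %in% inside$sequence)
  }
})

test_that("a region that fits one module yields a single-module plan", {
  es <- fix_es()
  plan <- plan_partition(strrep("A", 600), c(1, 600), planner_config(), es)
  expect_equal(nrow(plan$modules), 1L)
  expect_equal(nrow(plan$junctions), 0L)
  expect_equal(classify_junctions(plan), c(n_palindromic = 0L, n_hybrid = 0L))
  expect_equal(plan$modules$length, 600L)
  expect_true(plan$safety$clean)
})

test_that("a junction enzyme cutting inside its module disqualifies the candidate", {
  es <- fix_es()
  ## the only window candidate is NcoI/PciI at 1000, but NcoI also cuts at 300
  s <- planted_background(1600, c(300, 1000), c("CCATGG", "CCATGT"))
  expect_error(plan_partition(s, c(1, 1600), planner_config(), es),
               "NoJunctionFound")
  ## without the internal NcoI site the same layout plans fine
  s2 <- planted_background(1600, 1000, "CCATGT")
  plan <- plan_partition(s2, c(1, 1600), planner_config(), es)
  expect_equal(plan$junctions$position, 1000L)
})

test_that("strict mode rejects reuse of the 5'-terminal enzyme; lenient permits and reports", {
  es <- fix_es()
  s <- planted_background(1600, 1000, "CTCGAC")  # XhoI/SalI hybrid
  cfg_strict <- planner_config(terminal_5 = "XhoI", terminal_3 = "NcoI")
  expect_error(plan_partition(s, c(1, 1600), cfg_strict, es), "NoJunctionFound")
  cfg_lenient <- planner_config(terminal_5 = "XhoI", terminal_3 = "NcoI",
                                strict_sequential = FALSE)
  plan <- plan_partition(s, c(1, 1600), cfg_lenient, es)
  expect_equal(plan$junctions$left_enzyme, "XhoI")
  expect_true(plan$safety$clean)  # lenient static check permits the reuse
  ## the sequential simulation still flags the terminal-site re-cut
  res <- simulate_assembly(plan, s)
  expect_false(res$report$clean)
  expect_equal(res$report$violations$context, "terminal-5 primer site")
  ## and matches the strict static analysis
  strict_rep <- assembly_safety_check(plan, s, strict = TRUE)
  expect_equal(res$report$violations, strict_rep$violations)
})

test_that("a terminal enzyme with an internal site is rejected at plan time", {
  es <- fix_es()
  s <- planted_background(900, c(200, 700), c("CCATGG", "GGATCC"))
  expect_error(
    plan_partition(s, c(1, 900), planner_config(terminal_5 = "NcoI"), es),
    "terminal enzyme NcoI cuts inside the region")
})

test_that("primer termini complete hybrid junction sites and leave palindromic ones genomic", {
  es <- fix_es()
  ## CCTAGA = AvrII (left) / XbaI (right) hybrid
  s <- planted_background(1600, 800, "CCTAGA")
  plan <- plan_partition(s, c(1, 1600), planner_config(), es)
  expect_equal(plan$junctions$sequence, "CCTAGA")
  expect_equal(unname(primer_termini(plan, 1)["right_added"]), "G")  # ...CCTAG + G = AvrII site
  expect_equal(unname(primer_termini(plan, 2)["left_added"]), "T")   # T + CTAGA... = XbaI site
  ## palindromic junction: nothing added
  s2 <- planted_background(1600, 800, "GGATCC")
  plan2 <- plan_partition(s2, c(1, 1600), planner_config(), es)
  expect_equal(plan2$junctions$kind, "palindromic")
  expect_equal(unname(primer_termini(plan2, 1)), c("", ""))
  expect_equal(unname(primer_termini(plan2, 2)), c("", ""))
  expect_error(primer_termini(plan2, 9), "no such module")
})

test_that("worked-example tables reconstruct to 3 palindromic and 6 hybrid junctions", {
  es <- fix_es()
  tabs <- chef1_module_tables()
  ju <- junctions_from_module_table(tabs$upstream, es)
  jd <- junctions_from_module_table(tabs$downstream, es)
  expect_equal(ju$kind, c("hybrid", "palindromic", "hybrid", "hybrid"))
  expect_equal(jd$kind, c("hybrid", "hybrid", "palindromic", "palindromic", "hybrid"))
  all9 <- rbind(ju, jd)
  expect_equal(classify_junctions(all9),
               c(n_palindromic = 3L, n_hybrid = 6L))
  ## printed consecutive coordinates overlap by exactly the junction width
  expect_equal(all9$observed_overlap, all9$overlap_len)
  ## junction sequences from the flanking enzymes
  expect_equal(ju$sequence, c("CCTAGA", "GGATCC", "CCTAGT", "CTCGAC"))
  expect_equal(jd$sequence, c("TCTAGC", "CCTAGC", "CCTAGG", "GAGCTC", "GGATCA"))
})

test_that("printed module coordinates are length-consistent (one known off-by-one)", {
  tabs <- chef1_module_tables()
  up <- tabs$upstream; dn <- tabs$downstream
  expect_equal(module_length(up$start, up$end), up$length)
  expect_equal(module_length(dn$start, dn$end)[1:5], dn$length[1:5])
  ## the final downstream row prints 780 for an 18016-18794 span of 779 bp
  expect_equal(module_length(dn$start[6], dn$end[6]), 779L)
  expect_equal(dn$length[6], 780L)
})
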