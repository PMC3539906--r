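---
title: "Modular assembly cloning: hybrid sites, module planning, and in-silico verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular assembly cloning: hybrid sites, module planning, and in-silico verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macplan)
```

## The problem

Cloning a genomic DNA fragment longer than about 3-5 kbp by direct PCR is
unreliable: long amplicons are hard to obtain at all, polymerase errors
accumulate with length and cycle number, and verifying a long insert
requires many custom sequencing primers. Modular assembly cloning (MAC)
side-steps this by dividing the target into modules of roughly 500-1300 bp,
each short enough to amplify robustly and to sequence completely with
generic vector primers, and then reassembling the verified modules by
restriction digestion and sticky-end ligation. Because restriction-ligation
essentially never introduces point mutations, the assembled product needs
no re-sequencing.

The crux is the junctions. A natural junction is a palindromic hexamer
recognition site shared by both neighbouring modules. But `macplan`'s
central device is the **hybrid site**: two different enzymes whose
palindromic sites leave the *same* 4-base 5' overhang (isocaudomers) can be
ligated across a junction, and the product hexamer --
`left.site[1] + overhang + right.site[6]` -- is non-palindromic. NcoI
(`C^CATGG`) and PciI (`A^CATGT`) both leave `CATG`; ligating an NcoI end to
a PciI end reads `CCATGT`, which neither parent enzyme (nor any enzyme with
a palindromic hexamer site) can cut. A hybrid junction is therefore *inert
once formed*: further occurrences of the same hybrid hexamer elsewhere in
the target cost nothing, and later assembly steps cannot re-open it.

## Site statistics in random DNA

Under a uniform i.i.d. base model, a fixed hexamer matches at any given
offset with probability $p = 4^{-6} = 1/4096$. `macplan` counts
$n = L - 6 + 1$ overlapping window starts in a fragment of length $L$ and
treats them as independent binomial trials:

* `prob_no_site(L)` $= (1-p)^n$ — the chance a given enzyme is unusable on
  the fragment (29.5% at $L = 5000$);
* `prob_multi_site(L)` $= 1 - (1-p)^n - np(1-p)^{n-1}$ (34.4% at
  $L = 5000$);
* `prob_at_least_one(L)` — the chance a junction enzyme also cuts inside
  its own module, the one real constraint on hybrid junctions. Both the
  exact form and the linear union bound $\min(1, Lp)$ are exposed; the
  familiar working figures of 25% per 1000 bp and 12.5% per 500 bp are the
  linear bound rounded up (24.41% and 12.21%).

Two conventions were open. First, the trial count: $n = L - 5$ versus
$n = L$; both round to 29.5% absence at 5 kb and differ only in the third
digit of the multiplicity figure. We fix $n = L - 5$, the exact window
count. Second, independence of overlapping windows is an approximation
(overlapping-word correlations exist); `monte_carlo_site_freq()` quantifies
it by seeded simulation, and the suite checks agreement within 3 standard
errors at 2000 replicates. A Markov or GC-adjusted null is deliberately out
of scope — the binomial model is the model in use.

There are $4^3 = 64$ palindromic hexamers, so some palindromic site is
expected about every 64 bp. The hybrid space — all hexamers whose central
tetramer is palindromic — has $4^2 \times 4^2 = 256$ members, one expected
every `expected_spacing(256)` = 16 bp: a four-fold denser grid of candidate
junctions, which is what makes flexible module boundaries practical.

## The enzyme table

Enzymes are loaded from a delimited text table with three mandatory fields
(name, recognition site, cohesive end) and optional `end_type`, `dam`,
`dcm` columns. Scope is deliberately narrow: non-ambiguous palindromic
hexamer sites. Rows with ambiguity codes, non-hexamer or non-palindromic
sites are skipped with a warning rather than aborting the load, so one bad
row cannot block a mapping run. Cut geometry is derived from the site and
end type by the mirror rule (`derive_overhang()`); when the table also
carries a cohesive-end value it is validated against the derived one and a
mismatch is a hard, row-naming error — silently trusting either source
seemed worse than refusing. A missing end type defaults to the 5', 4-base,
cut-offset-1 convention, by far the common case in this site class.
Isoschizomers (identical site and geometry) merge into one record carrying
synonyms, so AhlI resolves to SpeI. Enzymes generating 3' overhangs (SacI)
or blunt ends are retained for mapping and may serve at palindromic
junctions (3' only — blunt ends cannot be ligated back seamlessly in this
scheme), but never enter hybrid generation, which is restricted to 4-base
5' overhangs.

Dam/Dcm flags: an explicit table column wins; otherwise a context heuristic
flags sites containing `GATC` (Dam) or `CCAGG`/`CCTGG` (Dcm). The heuristic
is advisory — flanking-dependent sensitivity is not modelled — which is
exactly why the bundled table carries explicit values (BamHI contains
`GATC` but is not Dam-blocked; BclI is).

## Scanning

Input cleaning accepts single-record FASTA or pasted text, strips digits
and whitespace (so numbered GenBank-style listings paste cleanly),
uppercases, and rejects anything outside A/C/G/T. Ambiguity codes are
rejected rather than wildcarded: a site call through an `N` is not a
mappable junction. Coordinates are 1-based and inclusive throughout,
matching the worked-example tables.

`scan_sites()` reports *every* occurrence, including overlapping ones.
Only the forward strand is scanned: palindromic sites are strand-symmetric
by definition, and for hybrids both orientations of each ordered enzyme
pair are generated (`sequence(A,B) = revcomp(sequence(B,A))`), so
forward-strand scanning over ordered pairs covers both strands. This
orientation duality is checked exhaustively in the test suite, and the
scanner as a whole is checked against a brute-force substring oracle on
seeded random sequences. Hybrid sequences reachable from several ordered
pairs are reported once per position with all pairs listed.

## Planning a partition

`plan_partition()` walks the region left to right. With less than
`max_module` bp remaining it closes the final module; otherwise it collects
every palindromic and hybrid site whose position keeps the current module
inside `[min_module, max_module]` and ranks candidates by distance from the
ideal module end, palindromic before hybrid on ties (a palindromic junction
needs no corrective primer base), then lexicographic enzyme name. The
search backtracks when a later window is unsatisfiable, and is entirely
deterministic for a fixed input. Defaults are 500/750/1300 bp
(min/ideal/max): the working range is 500-1000 bp, with headroom because a
sparse site landscape occasionally forces a longer module — the worked
example's largest module is 1287 bp.

A candidate junction must pass the no-internal-cut checks before adoption:

* the enzyme cutting each module end has no recognition-site occurrence
  inside that module other than the one its digestion step targets;
* in strict mode (`strict_sequential = TRUE`, the default), the enzyme that
  cuts the *growing assembly* at step $k$ must be absent from everything
  already assembled — earlier modules, restored palindromic junctions, and
  the 5'-terminal primer site — so that each step cuts exactly two adjacent
  pieces;
* configured terminal enzymes must not cut anywhere inside the region.

One subtlety is deliberately stricter than a naive reading of "ignore the
junction sites at the module's own termini". A module's 5' digestion
exempts only the occurrence at its 5' terminus; an occurrence of the same
enzyme's site at the module's *3'* end (including the site completed by the
primer-added outer base at a hybrid junction) really would be cut one step
early, truncating the module, so the planner rejects it and the safety
analysis reports it. Lenient mode (`strict_sequential = FALSE`) checks only
the adjacent modules — it exists because real bench plans do reuse
enzymes across non-adjacent steps (e.g. a terminal site sharing its enzyme
with an interior junction) and such reuse can be managed at the bench by
partial digestion or assembly order; the simulation still reports it.

Module coordinates follow the junction geometry: a palindromic junction's
full 6-mer is genomic in both modules (6-bp overlap; next module starts on
the site), a hybrid junction shares only its central 4-base overhang (4-bp
overlap), and each side's missing outer base is supplied by the PCR primer
(`primer_termini()`), so that after cutting and ligation the genomic text
is restored exactly.

## In-silico verification

`simulate_assembly()` re-plays the bench protocol: build each amplicon
(genomic span plus primer-added bases), digest the growing assembly's right
end with the junction's left enzyme, digest the incoming module's left end
with the right enzyme, check overhang compatibility and polarity, ligate.
Fragments model the duplex by top strand plus end annotations; symmetric
type II cuts split the top strand at one point per site, so digestion
followed by in-order ligation reconstructs any input exactly (a tested
invariant). The simulation follows the intended cut even when off-target
cuts occur, recording every one, so a single run reports all problems; a
digestion that fails to cut at its intended junction is an error. The
product is compared byte-for-byte against the target region —
seamlessness is the point of the whole construction.

`assembly_safety_check()` derives the same report without simulating cuts:
in strict mode it scans exactly the strings the sequential assembly would
digest, so its report provably equals the dynamic one; the suite asserts
this equality on clean and on adversarial plans. Linear DNA only; the
vector backbone is abstracted away, and the assembly order is the
sequential left-to-right order — alternative bench orders are not
simulated.

## Synthetic data: what it emulates and what it does not

All tests run without downloads, on three generator layers:

* `random_sequence()` — uniform i.i.d. DNA, the statistics null model;
* `plant_sites()` / `scrub_sites()` — write motifs at chosen positions /
  deterministically mutate away all unwanted site occurrences, giving a
  fully controlled site landscape;
* `plannable_target()` — a scrubbed background with one junction planted
  roughly every 750 bp (±40 bp seeded jitter), rotating through enzyme
  pairs from distinct compatibility classes plus palindromic EcoRI/SacI
  junctions, so strict sequential assembly is satisfiable by construction;
* `surrogate_target()` — the printed worked-example junction hexamers laid
  onto a random background at the printed relative offsets.

These emulate site geometry, not biology: real genomic sequence has biased
composition, repeats, and a denser, less convenient site landscape in which
the planner must actually reject candidates and backtrack. Passing the
seamlessness property on synthetic targets shows the geometry, constraint
logic and cut/ligation model are exact; it does not show that any
particular natural region admits a partition. Surrogate targets carry
printed junction geometry only — tests against them may assert coordinates
and classification, never residue content. The published module tables are
shipped verbatim as fixtures; one printed length (the final downstream
module, 780) disagrees by one with its own coordinates (18016-18794 spans
779 bp under the 1-based inclusive convention all other rows obey), and the
tests pin both numbers explicitly.

## Numerical and degenerate-input choices

* Overlapping occurrences are all reported; a hexamer can start at
  consecutive offsets.
* A region at most `max_module` long yields a single-module plan; shorter
  than `min_module` it is flagged `short` rather than refused.
* The planner's backtracking is bounded (20 000 node expansions) so a
  pathological site landscape fails fast with `NoJunctionFound` naming the
  window, rather than exploding.
* `scrub_sites()` accepts a mutation only if it removes its target
  occurrence without creating any other (checked in a local window), which
  guarantees the global occurrence count strictly decreases — the
  deterministic base-cycling alternative can oscillate.
* Sites straddling a primer-added outer base at an off-intended offset
  require internal site periodicity (none of the bundled enzymes has any);
  the strict safety check and the simulation handle them by scanning the
  composed amplicon strings rather than genomic coordinates.
* Seeded randomness never touches the caller's RNG stream.
* Problem sizes in the suite: the scanner oracle runs 100 seeded sequences
  of 60-2000 bp; the seamlessness property runs 50 seeded targets of 2-5
  modules; the Monte Carlo check uses 2000 replicates of 5000 bp. These
  sizes put every stochastic check at least three standard errors from its
  threshold while keeping the suite quick.

## Limitations

Nicking and Type IIS (shifted-cut) enzymes, sites other than non-ambiguous
hexamer palindromes, overhangs other than 0/4 bases, circular targets,
multi-record FASTA, partial digestion, dephosphorylation, blunt ligation
and primer thermodynamics are out of scope. The occurrence model is
binomial-uniform by design. The report layout is a documented format of
this package, not a byte-faithful clone of any predecessor tool's screen
output.
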