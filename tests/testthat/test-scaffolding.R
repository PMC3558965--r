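# Enumeration oracle for a junction joining the original tail of the
# upstream contig to the original head of the downstream one: the emitted
# junction sides follow from the emission strands, and the class follows
# from the sides (sides differ -> colinear "same"; tail-tail ->
# "converging"; head-head -> "diverging").
junction_class <- function(strand_up, strand_down) {
  side_up <- if (strand_up == "+") "tail" else "head"
  side_down <- if (strand_down == "+") "head" else "tail"
  if (side_up != side_down) "same"
  else if (side_up == "tail") "converging" else "diverging"
}

test_that("junction pairs classify per the four-emission enumeration oracle", {
  cfg <- sim_config(genome_len = 40000L, pair_count = 4000L, seed = 301L)
  mod <- simulate_reference(cfg)
  # two-contig toy genome: cut the circle in half ourselves so that every
  # emission strand combination can be forced
  half1 <- substring(mod$reference$seq, 1, 20000)
  half2 <- substring(mod$reference$seq, 20001, 40000)
  sim <- simulate_mate_pairs(mod, cfg)
  for (s1 in c("+", "-")) for (s2 in c("+", "-")) {
    contigs <- list(
      seq_record("ctgA", if (s1 == "+") half1 else revcomp(half1)),
      seq_record("ctgB", if (s2 == "+") half2 else revcomp(half2)))
    idx <- build_index(contigs, k = 25)
    mp <- map_pairs(idx, sim$pairs)
    lens <- c(ctgA = 20000L, ctgB = 20000L)
    cl <- classify_relative_orientation(mp$pairs, cfg$library, lens)
    inter <- cl[cl$kind == "inter", ]
    expect_gt(nrow(inter), 100)
    # the circle has two junctions (A-tail|B-head and B-tail|A-head), each
    # with its own expected class; with one contig flipped they split into
    # converging at one junction and diverging at the other
    expected <- c(junction_class(s1, s2), junction_class(s2, s1))
    expect_setequal(unique(inter$orientation), unique(expected))
    if (s1 != s2) expect_gt(min(table(inter$orientation)), 0.2 * nrow(inter))
  }
})

test_that("intra-contig pairs classify concordant by definition", {
  cfg <- sim_config(genome_len = 30000L, pair_count = 300L, seed = 311L)
  mod <- simulate_reference(cfg)
  one <- fragment_into_contigs(mod, 1L, seed = 312L)  # single linear contig
  sim <- simulate_mate_pairs(mod, cfg)
  idx <- build_index(one$contigs, k = 25)
  mp <- map_pairs(idx, sim$pairs)
  lens <- setNames(one$contigs[[1]]$length, names(one$contigs))
  cl <- classify_relative_orientation(mp$pairs, cfg$library, lens)
  expect_gt(nrow(cl), 200)
  expect_true(all(cl$kind == "intra"))
  # every pair is concordant except the few whose fragment wraps the point
  # where the circle was linearised into the contig
  conc <- cl$category == "concordant"
  L <- unname(lens)
  wraps <- pmin(cl$pos1, cl$pos2) < 3500 & pmax(cl$pos1, cl$pos2) > L - 3500
  expect_true(all(conc | wraps))
  expect_gt(mean(conc), 0.85)
  expect_true(all(cl$implied_insert[conc] >= 1000L &
                  cl$implied_insert[conc] <= 3500L))
})

test_that("From::To table conserves counts and is empty on no input", {
  cfg <- sim_config(genome_len = 60000L, physical_coverage = 8, seed = 321L)
  mod <- simulate_reference(cfg)
  fr <- fragment_into_contigs(mod, 4L, seed = 322L)
  sim <- simulate_mate_pairs(mod, cfg)
  idx <- build_index(fr$contigs, k = 25)
  mp <- map_pairs(idx, sim$pairs)
  lens <- setNames(vapply(fr$contigs, `[[`, 1L, "length"), names(fr$contigs))
  tab <- accumulate_from_to_table(mp$pairs, cfg$library, lens)
  expect_identical(sum(tab$cells$count), tab$n_inter)
  expect_identical(tab$n_inter + tab$n_intra, nrow(mp$pairs))
  ft <- from_to_matrix(tab)
  expect_identical(sum(ft$count), tab$n_inter)
  expect_true(all(ft$orientation %in% c("same", "converging", "diverging")))

  empty <- accumulate_from_to_table(mp$pairs[0, ], cfg$library, lens)
  expect_identical(nrow(empty$cells), 0L)
  expect_identical(empty$n_inter, 0L)
})

test_that("a 2-contig toy genome yields a single dominant cell per junction", {
  cfg <- sim_config(genome_len = 30000L, pair_count = 1000L, seed = 331L)
  mod <- simulate_reference(cfg)
  fr <- fragment_into_contigs(mod, 2L, seed = 332L)
  sim <- simulate_mate_pairs(mod, cfg)
  idx <- build_index(fr$contigs, k = 25)
  mp <- map_pairs(idx, sim$pairs)
  lens <- setNames(vapply(fr$contigs, `[[`, 1L, "length"), names(fr$contigs))
  tab <- accumulate_from_to_table(mp$pairs, cfg$library, lens)
  # error-free: only the two true junction cells exist
  expect_lte(nrow(tab$cells), 2L)
  expect_gt(min(tab$cells$count), 10L)
})

test_that("build_scaffold closes a 20-contig circle and respects thresholds", {
  cfg <- sim_config(genome_len = 300000L, physical_coverage = 10, seed = 341L)
  mod <- simulate_reference(cfg)
  fr <- fragment_into_contigs(mod, 20L, seed = 342L)
  sim <- simulate_mate_pairs(mod, cfg)
  idx <- build_index(fr$contigs, k = 25)
  mp <- map_pairs(idx, sim$pairs)
  lens <- setNames(vapply(fr$contigs, `[[`, 1L, "length"), names(fr$contigs))
  tab <- accumulate_from_to_table(mp$pairs, cfg$library, lens)
  sc <- build_scaffold(tab, lens, min_support = 2L)
  expect_true(scaffold_matches_truth(sc, fr$layout))

  # all counts below threshold: every contig is its own linear scaffold
  expect_warning(none <- build_scaffold(tab, lens, min_support = 10000L),
                 "did not close")
  expect_identical(length(none$scaffolds), 20L)

  # single contig: trivially circular
  one <- fragment_into_contigs(mod, 1L, seed = 343L)
  lens1 <- setNames(one$contigs[[1]]$length, names(one$contigs))
  sim1 <- simulate_mate_pairs(mod, cfg)
  idx1 <- build_index(one$contigs, k = 25)
  mp1 <- map_pairs(idx1, sim1$pairs)
  tab1 <- accumulate_from_to_table(mp1$pairs, cfg$library, lens1)
  sc1 <- build_scaffold(tab1, lens1, min_support = 2L)
  expect_identical(length(sc1$scaffolds), 1L)
  expect_true(sc1$scaffolds[[1]]$circular)
})

test_that("reverse-complementing every contig reflects the scaffold", {
  cfg <- sim_config(genome_len = 100000L, physical_coverage = 12, seed = 351L)
  mod <- simulate_reference(cfg)
  fr <- fragment_into_contigs(mod, 6L, seed = 352L)
  sim <- simulate_mate_pairs(mod, cfg)
  lens <- setNames(vapply(fr$contigs, `[[`, 1L, "length"), names(fr$contigs))

  sc_fwd <- local({
    idx <- build_index(fr$contigs, k = 25)
    mp <- map_pairs(idx, sim$pairs)
    build_scaffold(accumulate_from_to_table(mp$pairs, cfg$library, lens),
                   lens, min_support = 2L)
  })
  sc_rc <- local({
    flipped <- lapply(fr$contigs, function(r)
      seq_record(r$id, revcomp(r$seq), r$circular))
    idx <- build_index(flipped, k = 25)
    mp <- map_pairs(idx, sim$pairs)
    build_scaffold(accumulate_from_to_table(mp$pairs, cfg$library, lens),
                   lens, min_support = 2L)
  })
  o1 <- sc_fwd$scaffolds[[1]]$order
  o2 <- sc_rc$scaffolds[[1]]$order
  expect_true(sc_fwd$scaffolds[[1]]$circular && sc_rc$scaffolds[[1]]$circular)
  # flipping every contig flips every strand; canonicalisation then reflects
  # the cycle, so the contig sequence must match up to rotation/reflection
  lay1 <- data.frame(contig_id = o2$contig_id,
                     strand = ifelse(o2$strand == "+", "-", "+"),
                     order = seq_len(nrow(o2)))
  expect_true(scaffold_matches_truth(sc_fwd, lay1))
})

test_that("gap estimates recover true gaps without length bias", {
  for (true_gap in c(0L, 500L)) {
    cfg <- sim_config(genome_len = 200000L, physical_coverage = 60,
                      seed = 360L + true_gap)
    mod <- simulate_reference(cfg)
    fr <- fragment_into_contigs(mod, 4L, seed = 361L, gap = true_gap)
    sim <- simulate_mate_pairs(mod, cfg)
    idx <- build_index(fr$contigs, k = 25)
    mp <- map_pairs(idx, sim$pairs)
    lens <- setNames(vapply(fr$contigs, `[[`, 1L, "length"), names(fr$contigs))
    tab <- accumulate_from_to_table(mp$pairs, cfg$library, lens)
    sc <- build_scaffold(tab, lens, min_support = 2L)
    g <- estimate_gaps(mp$pairs, sc, cfg$library, lens)
    expect_identical(nrow(g), 4L)
    expect_gt(min(g$n_pairs), 20L)
    # allow ~3 standard errors, plus the inverse-mapping slope
    expect_true(all(abs(g$gap_est - true_gap) < 3 * 1.5 * g$gap_se + 20))
  }

  # junction without spanning pairs reports unknown
  lens <- c(a = 10000L, b = 10000L)
  tab0 <- accumulate_from_to_table(
    data.frame(pair_id = character(), seq1 = character(), pos1 = integer(),
               strand1 = character(), seq2 = character(), pos2 = integer(),
               strand2 = character()), library_spec(), lens)
  sc0 <- suppressWarnings(build_scaffold(tab0, lens, min_support = 1L))
  g0 <- estimate_gaps(
    data.frame(pair_id = character(), seq1 = character(), pos1 = integer(),
               strand1 = character(), seq2 = character(), pos2 = integer(),
               strand2 = character()), sc0, library_spec(), lens)
  expect_identical(nrow(g0), 0L)
})

test_that("AGP and scaffold FASTA exports are structurally sound", {
  cfg <- sim_config(genome_len = 60000L, physical_coverage = 15, seed = 371L)
  mod <- simulate_reference(cfg)
  fr <- fragment_into_contigs(mod, 4L, seed = 372L)
  sim <- simulate_mate_pairs(mod, cfg)
  idx <- build_index(fr$contigs, k = 25)
  mp <- map_pairs(idx, sim$pairs)
  lens <- setNames(vapply(fr$contigs, `[[`, 1L, "length"), names(fr$contigs))
  tab <- accumulate_from_to_table(mp$pairs, cfg$library, lens)
  sc <- build_scaffold(tab, lens, min_support = 2L)
  gaps <- estimate_gaps(mp$pairs, sc, cfg$library, lens)

  agp <- withr::local_tempfile(fileext = ".agp")
  write_agp(sc, lens, gaps, agp)
  lines <- readLines(agp)
  expect_identical(lines[1], "##agp-version\t2.1")
  comp <- lines[grepl("\tW\t", lines)]
  expect_identical(length(comp), 4L)

  seqs <- scaffold_sequence(sc, fr$contigs, gaps)
  expect_identical(length(seqs), 1L)
  expect_true(seqs[[1]]$circular)
  # abutting contigs: reconstructed length within estimation noise of truth
  expect_lt(abs(seqs[[1]]$length - 60000L) / 60000, 0.02)
})
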