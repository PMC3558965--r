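test_that("pair classes partition all intra-chromosome unique pairs", {
  lc <- inversion_locus(20000, 40000, 0.4, flank_repeat_len = 100L)
  ex <- sim_experiment(genome_len = 80000L, pair_count = 8000L,
                       loci = list(lc), seed = 401L)
  cl <- classify_chromosome_pairs(ex$mp$pairs, ex$cfg$library, 80000L)
  expect_identical(nrow(cl), nrow(ex$mp$pairs))
  expect_true(all(cl$class %in% c("concordant", "inverted", "other_discordant")))
  inv <- collect_inverted_pairs(ex$mp$pairs, ex$cfg$library, 80000L)
  expect_identical(nrow(inv),
                   sum(cl$class == "inverted"))
  expect_gt(nrow(inv), 50)
  # strand signature: inverted pairs have opposite strands, concordant equal
  expect_true(all(inv$strand1 != inv$strand2))
  conc <- cl[cl$class == "concordant", ]
  expect_true(all(conc$strand1 == conc$strand2))
})

test_that("a clonal population yields no inverted evidence and no calls", {
  ex <- sim_experiment(genome_len = 60000L, pair_count = 5000L, seed = 411L)
  inv <- collect_inverted_pairs(ex$mp$pairs, ex$cfg$library, 60000L)
  expect_identical(nrow(inv), 0L)
  calls <- call_inversions(ex$mp$pairs, ex$cfg$library, 60000L)
  expect_identical(nrow(calls), 0L)
  # frequency-zero loci behave identically
  lc <- inversion_locus(20000, 35000, 0, flank_repeat_len = 50L)
  ex0 <- sim_experiment(genome_len = 60000L, pair_count = 5000L,
                        loci = list(lc), seed = 412L)
  expect_identical(nrow(call_inversions(ex0$mp$pairs, ex0$cfg$library, 60000L)), 0L)
})

test_that("one inversion gives two breakpoint-side clusters, three give six", {
  lc <- inversion_locus(15000, 35000, 0.5, flank_repeat_len = 0L)
  ex <- sim_experiment(genome_len = 60000L, pair_count = 8000L,
                       loci = list(lc), seed = 421L)
  inv <- collect_inverted_pairs(ex$mp$pairs, ex$cfg$library, 60000L)
  cls <- cluster_breakpoints(inv, ex$cfg$library, 10L, 60000L)
  expect_identical(length(cls), 2L)
  expect_setequal(vapply(cls, `[[`, "", "side"), c("start", "end"))
  # inverted evidence concentrates within one insert of the true breakpoints
  st <- cls[[which(vapply(cls, `[[`, "", "side") == "start")]]
  expect_lt(abs(st$a_outer - 15000), 3500)

  loci3 <- example_inversion_loci(300000L)
  ex3 <- sim_experiment(genome_len = 300000L, pair_count = 60000L,
                        loci = loci3, seed = 422L)
  inv3 <- collect_inverted_pairs(ex3$mp$pairs, ex3$cfg$library, 300000L)
  cls3 <- cluster_breakpoints(inv3, ex3$cfg$library, 10L, 300000L)
  expect_identical(length(cls3), 6L)
  expect_identical(length(unique(vapply(cls3, `[[`, 0L, "group"))), 3L)

  expect_identical(length(cluster_breakpoints(inv[0, ], ex$cfg$library,
                                              10L, 60000L)), 0L)
})

test_that("cluster pairing matches sides within groups and reports orphans", {
  loci <- list(inversion_locus(50000, 90000, 0.3, 100L),
               inversion_locus(180000, 220000, 0.3, 100L))
  ex <- sim_experiment(genome_len = 300000L, pair_count = 60000L,
                       loci = loci, seed = 431L)
  inv <- collect_inverted_pairs(ex$mp$pairs, ex$cfg$library, 300000L)
  cls <- cluster_breakpoints(inv, ex$cfg$library, 10L, 300000L)
  pc <- pair_clusters_to_inversions(cls, ex$cfg$library, 300000L)
  expect_identical(nrow(pc$candidates), 2L)
  expect_identical(length(pc$orphans), 0L)
  got <- pc$candidates[order(pc$candidates$start), ]
  expect_true(all(abs(got$start - c(50000, 180000)) <= 3500))
  expect_true(all(abs(got$end - c(90000, 220000)) <= 3500))

  # a single orphan side yields zero candidates and one reported orphan
  one_side <- cls[1]
  pc1 <- pair_clusters_to_inversions(one_side, ex$cfg$library, 300000L)
  expect_identical(nrow(pc1$candidates), 0L)
  expect_identical(length(pc1$orphans), 1L)
})

test_that("Wilson interval matches the independent prop.test oracle", {
  est <- estimate_inversion_frequency(17, 83)
  expect_identical(est$frequency, 0.17)
  est0 <- estimate_inversion_frequency(0, 100)
  expect_identical(est0$frequency, 0)
  expect_identical(est0$ci_low, 0)

  for (case in list(c(35, 65), c(17, 83), c(2, 98), c(450, 550), c(100, 0))) {
    w <- estimate_inversion_frequency(case[1], case[2])
    pt <- stats::prop.test(case[1], sum(case), correct = FALSE)
    expect_equal(w$ci_low, pt$conf.int[1], tolerance = 1e-9)
    expect_equal(w$ci_high, pt$conf.int[2], tolerance = 1e-9)
  }
  # frozen reference values for the (35, 65) case, recomputed by hand from
  # the score formula: centre 0.3555, half-width 0.0919
  w35 <- estimate_inversion_frequency(35, 65)
  expect_equal(w35$ci_low, 0.2636, tolerance = 0.001)
  expect_equal(w35$ci_high, 0.4475, tolerance = 0.001)
  expect_error(estimate_inversion_frequency(0, 0), "zero")
})

test_that("call_inversions recovers interval and frequency at depth", {
  lc <- inversion_locus(60000, 150000, 0.35, flank_repeat_len = 500L)
  ex <- sim_experiment(genome_len = 300000L, pair_count = 120000L,
                       loci = list(lc), seed = 441L)
  calls <- call_inversions(ex$mp$pairs, ex$cfg$library, 300000L)
  expect_identical(nrow(calls), 1L)
  expect_lt(abs(calls$start - 60000), 200)
  expect_lt(abs(calls$end - 150000), 200)
  expect_lt(abs(calls$frequency - 0.35), 0.04)
  expect_true(calls$ci_low < 0.35 && 0.35 < calls$ci_high)
  expect_identical(calls$length, calls$end - calls$start + 1L)
  # uncertainty windows cover the truth and reflect the flank repeat
  expect_lte(calls$start_window_lo, 60000L)
  expect_gte(calls$end_window_hi, 150000L)

  # a frequency threshold above truth suppresses the call
  none <- call_inversions(ex$mp$pairs, ex$cfg$library, 300000L,
                          min_frequency = 0.5)
  expect_identical(nrow(none), 0L)

  # named via user annotations by maximal overlap
  ann <- data.frame(name = c("left_feature", "the_locus"),
                    start = c(1000L, 58000L), end = c(2000L, 152000L))
  named <- call_inversions(ex$mp$pairs, ex$cfg$library, 300000L,
                           annotations = ann)
  expect_identical(named$name, "the_locus")
})

test_that("an inversion spanning the circular origin is called with wrapped coordinates", {
  lc <- inversion_locus(40000, 55000, 0.4, flank_repeat_len = 0L)
  cfg <- sim_config(genome_len = 60000L, pair_count = 40000L, seed = 451L)
  mod <- simulate_reference(cfg, loci = list(lc))
  sim <- simulate_mate_pairs(mod, cfg)
  # map against a rotated copy of the chromosome, so that in the mapping
  # frame the locus straddles the origin: x' = ((x - rot_by - 1) mod L) + 1
  rot_by <- 47000L
  rot_seq <- paste0(substring(mod$reference$seq, rot_by + 1L),
                    substring(mod$reference$seq, 1L, rot_by))
  idx <- build_index(seq_record("chr", rot_seq, circular = TRUE), k = 25)
  mp <- map_pairs(idx, sim$pairs)
  calls <- call_inversions(mp$pairs, cfg$library, 60000L)
  expect_identical(nrow(calls), 1L)
  expect_gt(calls$start, calls$end)  # wrapped representation
  expect_lt(abs(calls$start - 53000), 300)
  expect_lt(abs(calls$end - 8000), 300)
  expect_identical(calls$length,
                   interval_length(calls$start, calls$end, seq_len = 60000L,
                                   circular = TRUE))
  expect_lt(abs(calls$frequency - 0.4), 0.04)
})

test_that("reverse-complementing the chromosome mirrors the calls", {
  lc <- inversion_locus(20000, 45000, 0.3, flank_repeat_len = 200L)
  cfg <- sim_config(genome_len = 90000L, pair_count = 50000L, seed = 461L)
  mod <- simulate_reference(cfg, loci = list(lc))
  sim <- simulate_mate_pairs(mod, cfg)
  L <- 90000L

  idx_f <- build_index(mod$reference, k = 25)
  calls_f <- call_inversions(map_pairs(idx_f, sim$pairs)$pairs,
                             cfg$library, L)
  mod_rc <- seq_record("chr", revcomp(mod$reference$seq), circular = TRUE)
  idx_r <- build_index(mod_rc, k = 25)
  calls_r <- call_inversions(map_pairs(idx_r, sim$pairs)$pairs,
                             cfg$library, L)
  expect_identical(nrow(calls_f), 1L)
  expect_identical(nrow(calls_r), 1L)
  expect_identical(calls_r$start, L - calls_f$end + 1L)
  expect_identical(calls_r$end, L - calls_f$start + 1L)
  expect_identical(calls_r$frequency, calls_f$frequency)
  expect_identical(calls_r$support_inverted, calls_f$support_inverted)
})

test_that("inversion calls export to BED and a summary table", {
  lc <- inversion_locus(30000, 60000, 0.3, flank_repeat_len = 0L)
  ex <- sim_experiment(genome_len = 120000L, pair_count = 40000L,
                       loci = list(lc), seed = 471L)
  calls <- call_inversions(ex$mp$pairs, ex$cfg$library, 120000L)
  expect_identical(nrow(calls), 1L)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(calls, bed)
  f <- strsplit(readLines(bed), "\t")[[1]]
  expect_identical(as.integer(f[2]) + 1L, calls$start)
  expect_identical(as.integer(f[3]), calls$end)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(calls, tsv)
  back <- read.delim(tsv)
  expect_identical(back$length, calls$length)
})
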