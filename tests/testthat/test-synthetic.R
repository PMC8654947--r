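test_that("library design enumerates all motif x position variants", {
  d <- make_design(10, 3, seed = 1)
  expect_equal(nrow(d$variants), 40)  # (3 motifs + control) x 10 positions
  expect_true(d$control_motif_id %in% d$motifs$motif_id)
  ctrl <- d$variants[d$variants$motif_id == d$control_motif_id, ]
  expect_setequal(ctrl$position, 1:10)
  expect_false(any(duplicated(d$variants[, c("position", "motif_id")])))
  # determinism
  expect_identical(make_design(10, 3, seed = 1), d)
  expect_false(identical(make_design(10, 3, seed = 2)$recipient_cds,
                         d$recipient_cds))
  # subpools partition the variants
  d2 <- make_design(10, 3, subpool_size = 20, seed = 1)
  expect_equal(length(unique(d2$variants$subpool)), 2)
  expect_equal(as.vector(table(d2$variants$subpool)), c(20, 20))
  expect_error(make_design(1, 3), "recipient_length")
  expect_error(make_design(10, 0), "n_motifs")
})

test_that("design sequences are coherent nucleotide/protein pairs", {
  d <- make_design(12, 4, seed = 5)
  expect_equal(nchar(d$recipient_cds), 36)
  expect_equal(nchar(d$recipient_aa), 12)
  expect_equal(nchar(d$motifs$nt_seq), 3 * d$motifs$length_aa)
  expect_equal(nchar(d$motifs$aa_seq), d$motifs$length_aa)
  expect_false(any(grepl("\\*", d$motifs$aa_seq)))
  ctrl <- d$motifs[d$motifs$motif_id == d$control_motif_id, ]
  expect_equal(ctrl$aa_seq, "AGSAGSA")
})

test_that("planted fitness surface has the configured cell structure", {
  d <- make_design(30, 10, seed = 2)
  # zero case: no effects, no noise
  z <- simulate_true_fitness(
    d, class_effects = c(rigid = 0, intermediate = 0, flexible = 0),
    group_effects = c(structured = 0, unstructured = 0, hydrophobic = 0),
    interaction_effects = matrix(0, 3, 3, dimnames = list(
      c("rigid", "intermediate", "flexible"),
      c("structured", "unstructured", "hydrophobic"))),
    noise_sd = 0, seed = 3)
  expect_true(all(z$fitness == 0))
  # planted cell means recovered exactly at zero noise
  inter <- matrix(0, 3, 3, dimnames = list(
    c("rigid", "intermediate", "flexible"),
    c("structured", "unstructured", "hydrophobic")))
  inter["rigid", "structured"] <- -3
  inter["flexible", "structured"] <- 2
  tr <- simulate_true_fitness(
    d, class_effects = c(rigid = 0, intermediate = 0, flexible = 0),
    group_effects = c(structured = 0, unstructured = 0, hydrophobic = 0),
    interaction_effects = inter, noise_sd = 0, seed = 3)
  m <- setdiff(names(which(tr$motif_group == "structured")),
               d$control_motif_id)[1]
  expect_false(is.na(m))
  rigid_pos <- names(which(tr$position_class == "rigid"))
  flex_pos <- names(which(tr$position_class == "flexible"))
  expect_true(all(tr$fitness[rigid_pos, m] == -3))
  expect_true(all(tr$fitness[flex_pos, m] == 2))
  # positions of each class form contiguous blocks
  for (cl in unique(tr$position_class)) {
    idx <- unname(which(tr$position_class == cl))
    expect_equal(idx, seq(min(idx), max(idx)))
  }
  # control column pinned at 0; reproducible given the seed
  expect_true(all(tr$fitness[, d$control_motif_id] == 0))
  expect_identical(simulate_true_fitness(d, seed = 9)$fitness,
                   simulate_true_fitness(d, seed = 9)$fitness)
  expect_error(simulate_true_fitness(d, class_fractions = c(a = .5, b = .4)),
               "sum to 1")
})

test_that("sort counts conserve reads and respond to the gate model", {
  d <- make_design(20, 5, seed = 4)
  tr <- simulate_true_fitness(d, seed = 5)
  sm <- sort_model(reads_per_gate = 5000, replicates = 2, dropout_rate = 0)
  cnt <- simulate_sort_counts(d, tr, sm, seed = 6)
  n_pools <- length(unique(d$variants$subpool))
  expect_equal(sum(cnt$count), 5000 * 2 * 2 * n_pools)
  expect_true(all(cnt$count >= 0))
  # with dropout, totals can only shrink
  cnt_d <- simulate_sort_counts(d, tr,
    sort_model(reads_per_gate = 5000, replicates = 2, dropout_rate = 0.2),
    seed = 6)
  expect_lte(sum(cnt_d$count), 5000 * 2 * 2 * n_pools)
  # zero reads -> all-zero table
  cnt0 <- simulate_sort_counts(d, tr, sort_model(reads_per_gate = 0), seed = 1)
  expect_true(all(cnt0$count == 0))
  # determinism
  expect_identical(simulate_sort_counts(d, tr, sm, seed = 6), cnt)
})

test_that("flat gate model distributes counts evenly between gates", {
  d <- make_design(10, 4, seed = 7)
  tr <- simulate_true_fitness(d, seed = 8)
  sm <- sort_model(gate_logit_slope = 0, reads_per_gate = 1e5,
                   replicates = 1, dropout_rate = 0)
  cnt <- simulate_sort_counts(d, tr, sm, seed = 9)
  tab <- stats::xtabs(count ~ paste(position, motif_id) + gate, data = cnt)
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_gt(p, 0.01)
})

test_that("higher true fitness yields higher high:low read ratios", {
  # Monte-Carlo contrast between a +5 and a -5 variant at unit slope
  d <- make_design(2, 1, seed = 10)
  tr <- simulate_true_fitness(d, noise_sd = 0, seed = 1)
  tr$fitness[1, 1] <- 5; tr$fitness[2, 1] <- -5
  wins <- 0L
  for (s in 1:100) {
    cnt <- simulate_sort_counts(d, tr,
      sort_model(reads_per_gate = 2000, replicates = 1, dropout_rate = 0),
      seed = s)
    g <- stats::xtabs(count ~ position + gate,
                      data = cnt[cnt$motif_id == colnames(tr$fitness)[1], ])
    r_hi <- (g["1", "high"] + 0.5) / (g["1", "low"] + 0.5)
    r_lo <- (g["2", "high"] + 0.5) / (g["2", "low"] + 0.5)
    if (r_hi > r_lo) wins <- wins + 1L
  }
  expect_gte(wins, 99)
})

test_that("read simulation conserves pairs and encodes correct junctions", {
  d <- make_design(60, 4, seed = 11)
  counts <- data.frame(position = c(5, 30, 55), motif_id = d$motifs$motif_id[1:3],
                       count = c(4, 3, 2))
  rd <- simulate_reads(d, counts, read_length = 100, seed = 12)
  expect_length(rd$fwd, sum(counts$count))
  expect_length(rd$rev, sum(counts$count))
  # error-free first mates contain the exact variant sequence around the
  # junction: verify each forward read occurs in its variant
  tru <- truth_from_names(names(rd$fwd))
  for (i in seq_along(rd$fwd)) {
    p <- tru$position[i]
    mnt <- d$motifs$nt_seq[d$motifs$motif_id == tru$motif_id[i]]
    varseq <- paste0(substr(d$recipient_cds, 1, 3 * p), mnt,
                     substr(d$recipient_cds, 3 * p + 1, nchar(d$recipient_cds)))
    expect_true(grepl(rd$fwd[[i]], varseq, fixed = TRUE))
  }
  expect_error(simulate_reads(d, counts, read_length = 20), "read_length")
})

test_that("substitution error rate matches the binomial expectation", {
  d <- make_design(60, 1, seed = 13)
  counts <- data.frame(position = 30, motif_id = d$motifs$motif_id[1],
                       count = 5000)
  clean <- simulate_reads(d, counts, read_length = 150, error_rate = 0, seed = 14)
  noisy <- simulate_reads(d, counts, read_length = 150, error_rate = 0.01, seed = 14)
  n_sub <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, clean$fwd, noisy$fwd)
  expect_gt(mean(n_sub), 1.5 * 0.9)
  expect_lt(mean(n_sub), 1.5 * 1.1)
})

test_that("property tables carry the configured couplings", {
  d <- make_design(100, 20, seed = 15)
  tr <- simulate_true_fitness(d, seed = 16)
  # null coupling: features independent of the truth
  p0 <- simulate_property_tables(d, tr, coupling = list(), n_nuisance = 8,
                                 seed = 17)
  cls <- as.integer(factor(tr$position_class))
  rhos <- vapply(grep("noise", names(p0$recipient), value = TRUE),
                 function(f) abs(stats::cor(p0$recipient[[f]], cls,
                                            method = "spearman")),
                 numeric(1))
  expect_gte(mean(rhos < 0.25), 0.9)
  # informative coupling separates classes
  p1 <- simulate_property_tables(d, tr, seed = 18)
  stiff <- p1$recipient$stiffness
  fit <- stats::aov(stiff ~ tr$position_class)
  expect_lt(summary(fit)[[1]][["Pr(>F)"]][1], 1e-10)
  # duplicated feature is an exact copy
  p2 <- simulate_property_tables(d, tr, duplicate_feature = TRUE, seed = 19)
  expect_identical(p2$recipient$stiffness, p2$recipient$stiffness_dup)
  expect_equal(stats::cor(p2$recipient$stiffness, p2$recipient$stiffness_dup), 1)
})

test_that("estimated fitness recovery improves with sequencing depth", {
  d <- make_design(40, 12, seed = 30)
  tr <- simulate_true_fitness(d, seed = 31)
  v <- d$variants[d$variants$motif_id != d$control_motif_id, ]
  tru <- tr$fitness[cbind(as.character(v$position), v$motif_id)]
  for (s in 1:3) {
    rhos <- vapply(c(2e3, 2e4, 2e5), function(depth) {
      cnt <- simulate_sort_counts(d, tr,
        sort_model(reads_per_gate = depth, replicates = 2, dropout_rate = 0),
        seed = 100 * s)
      sc <- score_counts(cnt, d$control_motif_id, min_fraction = NULL)
      est <- sc$fitness[cbind(as.character(v$position), v$motif_id)]
      ok <- !is.na(est)
      stats::cor(tru[ok], est[ok], method = "spearman")
    }, numeric(1))
    expect_true(all(diff(rhos) >= -0.005))
    expect_gt(rhos[3], rhos[1])
  }
})
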