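#' Design a synthetic domain-insertion library
#'
#' Builds an in-silico insertion library for a recipient coding sequence:
#' every donor motif (plus a flexible-linker control, amino-acid sequence
#' AGSAGSA) inserted after every recipient residue. Nucleotide sequences are
#' generated from random sense codons so that downstream read simulation and
#' junction calling operate on realistic exact-matchable sequence.
#'
#' @param recipient_length Number of recipient residues (insertion sites are
#'   "after residue i", i = 1..`recipient_length`).
#' @param n_motifs Number of donor motifs, excluding the control.
#' @param subpool_size Target number of variants per sequencing subpool;
#'   variants of a motif are kept in the same subpool. `NULL` puts everything
#'   in one subpool.
#' @param motif_length_range Range (amino acids) from which donor motif
#'   lengths are drawn uniformly.
#' @param seed Integer seed; the design is deterministic given the seed.
#' @return An object of class `dip_design`: list with `recipient_length`,
#'   `recipient_cds`, `recipient_aa`, `motifs` (data.frame: `motif_id`,
#'   `nt_seq`, `aa_seq`, `length_aa`), `variants` (data.frame: `position`,
#'   `motif_id`, `subpool`), and `control_motif_id`.
#' @export
make_design <- function(recipient_length, n_motifs, subpool_size = NULL,
                        motif_length_range = c(8, 40), seed = 1) {
  assert_that(is_count(recipient_length) && recipient_length >= 2,
              "recipient_length must be an integer >= 2")
  assert_that(is_count(n_motifs) && n_motifs >= 1,
              "n_motifs must be an integer >= 1")
  if (!is.null(subpool_size)) {
    assert_that(is_count(subpool_size) && subpool_size >= 1,
                "subpool_size must be a positive integer")
  }
  with_seed(seed, {
    cds <- random_cds(recipient_length)
    control_id <- "ctrl_AGSAGSA"
    control_nt <- "GCTGGTTCTGCTGGTTCTGCT"  # AGSAGSA
    lens <- sample(seq(motif_length_range[1], motif_length_range[2]),
                   n_motifs, replace = TRUE)
    motif_nt <- vapply(lens, random_cds, character(1))
    ids <- sprintf("motif_%03d", seq_len(n_motifs))
    motifs <- data.frame(
      motif_id = c(ids, control_id),
      nt_seq = c(motif_nt, control_nt),
      aa_seq = vapply(c(motif_nt, control_nt), translate_cds, character(1)),
      length_aa = c(lens, 7L),
      stringsAsFactors = FALSE
    )
    variants <- expand.grid(position = seq_len(recipient_length),
                            motif_id = motifs$motif_id,
                            KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
    # subpools partition variants, keeping each motif's positions together
    n_var <- nrow(variants)
    pool_of_motif <- if (is.null(subpool_size)) {
      stats::setNames(rep(1L, nrow(motifs)), motifs$motif_id)
    } else {
      motifs_per_pool <- max(1L, floor(subpool_size / recipient_length))
      stats::setNames(
        ((seq_len(nrow(motifs)) - 1L) %/% motifs_per_pool) + 1L,
        motifs$motif_id)
    }
    variants$subpool <- sprintf("pool%02d", pool_of_motif[variants$motif_id])
    structure(list(
      recipient_length = as.integer(recipient_length),
      recipient_cds = cds,
      recipient_aa = translate_cds(cds),
      motifs = motifs,
      variants = variants,
      control_motif_id = control_id,
      seed = as.integer(seed)
    ), class = "dip_design")
  })
}

# random coding sequence of n_aa sense codons (no stop codons)
random_cds <- function(n_aa) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_aa, replace = TRUE), collapse = "")
}

translate_cds <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAString(nt)))
}

#' @export
print.dip_design <- function(x, ...) {
  cat(sprintf(
    "<dip_design> %d positions x %d motifs (+control) = %d variants, %d subpool(s)\n",
    x$recipient_length, nrow(x$motifs) - 1L, nrow(x$variants),
    length(unique(x$variants$subpool))))
  invisible(x)
}

#' Plant a ground-truth fitness surface on a library design
#'
#' Simulates per-variant true surface-expression fitness as additive
#' position-class and motif-group effects plus a class-by-group interaction
#' and Gaussian noise. Position classes (rigid / intermediate / flexible)
#' occupy contiguous blocks of the recipient, mimicking contiguous structural
#' regions; the control motif has true fitness exactly 0 at every position,
#' matching its role as the normalisation anchor.
#'
#' @param design A `dip_design`.
#' @param class_fractions,group_fractions Named fractions (summing to 1) of
#'   positions per class and motifs per group.
#' @param class_effects,group_effects Named main effects on fitness.
#' @param interaction_effects Matrix (classes x groups) of interaction
#'   effects; defaults plant structured-at-flexible-termini gain,
#'   hydrophobic-in-rigid-core tolerance, and unstructured-in-rigid penalty.
#' @param noise_sd Standard deviation of i.i.d. Gaussian noise.
#' @param position_class,motif_group Optional explicit label vectors
#'   (overriding the random assignment; lengths `recipient_length` and
#'   number of non-control motifs).
#' @param seed Integer seed.
#' @return `dip_truth`: list with `position_class`, `motif_group`,
#'   `fitness` (positions x motifs matrix, control column all 0), `params`.
#' @export
simulate_true_fitness <- function(
    design,
    class_fractions = c(rigid = 0.4, intermediate = 0.3, flexible = 0.3),
    group_fractions = c(structured = 0.3, unstructured = 0.45, hydrophobic = 0.25),
    class_effects = c(rigid = -3, intermediate = -1, flexible = 1),
    group_effects = c(structured = -0.3, unstructured = 0.3, hydrophobic = -0.8),
    interaction_effects = NULL,
    noise_sd = 0.5,
    position_class = NULL,
    motif_group = NULL,
    seed = 1) {
  stopifnot(inherits(design, "dip_design"))
  assert_that(abs(sum(class_fractions) - 1) < 1e-8,
              "class_fractions must sum to 1")
  assert_that(abs(sum(group_fractions) - 1) < 1e-8,
              "group_fractions must sum to 1")
  classes <- names(class_fractions)
  groups <- names(group_fractions)
  if (is.null(interaction_effects)) {
    interaction_effects <- matrix(0, length(classes), length(groups),
                                  dimnames = list(classes, groups))
    if (all(c("flexible", "rigid") %in% classes) &&
        all(c("structured", "unstructured", "hydrophobic") %in% groups)) {
      interaction_effects["flexible", "structured"] <- 1.2
      interaction_effects["rigid", "hydrophobic"] <- 0.8
      interaction_effects["rigid", "unstructured"] <- -0.8
    }
  }
  stopifnot(identical(rownames(interaction_effects), classes),
            identical(colnames(interaction_effects), groups))
  L <- design$recipient_length
  other <- setdiff(design$motifs$motif_id, design$control_motif_id)
  with_seed(seed, {
    if (is.null(position_class)) {
      sizes <- largest_remainder(class_fractions * L)
      order_cls <- sample(classes)
      position_class <- rep(order_cls, sizes[order_cls])
    }
    stopifnot(length(position_class) == L, all(position_class %in% classes))
    if (is.null(motif_group)) {
      gsz <- largest_remainder(group_fractions * length(other))
      motif_group <- sample(rep(groups, gsz[groups]))
    }
    stopifnot(length(motif_group) == length(other), all(motif_group %in% groups))
    names(motif_group) <- other
    names(position_class) <- seq_len(L)

    fitness <- matrix(NA_real_, L, nrow(design$motifs),
                      dimnames = list(seq_len(L), design$motifs$motif_id))
    for (m in other) {
      g <- motif_group[[m]]
      mu <- class_effects[position_class] + group_effects[[g]] +
        interaction_effects[position_class, g]
      fitness[, m] <- mu + stats::rnorm(L, 0, noise_sd)
    }
    fitness[, design$control_motif_id] <- 0
    structure(list(
      position_class = position_class,
      motif_group = c(motif_group,
                      stats::setNames("unstructured", design$control_motif_id)),
      fitness = fitness,
      params = list(class_effects = class_effects,
                    group_effects = group_effects,
                    interaction_effects = interaction_effects,
                    noise_sd = noise_sd, seed = seed)
    ), class = "dip_truth")
  })
}

largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- sum(round(sum(x))) - sum(fl)
  if (rem > 0) {
    idx <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  stats::setNames(as.integer(fl), names(x))
}

#' Two-gate sort model parameters
#'
#' Parameters of the simulated surface-labelled high/low FACS sort.
#' The probability that a cell carrying a variant with true fitness f sorts
#' into the high (surface-expressed) gate is
#' `plogis(gate_logit_slope * f + gate_logit_intercept)` — a minimal monotone
#' link between fitness and the two-gate readout. Cell and read counts are
#' per gate, per replicate, per subpool.
#'
#' @param gate_logit_slope,gate_logit_intercept Logistic link parameters.
#' @param cells_per_gate,reads_per_gate Sorted cells / sequenced reads per
#'   gate, replicate and subpool.
#' @param replicates Number of independent sort replicates.
#' @param dropout_rate Fraction of library variants (the control is exempt)
#'   set to zero counts in each replicate, emulating structured missingness.
#' @return A `dip_sort_model` list.
#' @export
sort_model <- function(gate_logit_slope = 1, gate_logit_intercept = 0,
                       cells_per_gate = 2e5, reads_per_gate = 1e5,
                       replicates = 2, dropout_rate = 0.05) {
  assert_that(gate_logit_slope >= 0, "gate_logit_slope must be >= 0")
  assert_that(cells_per_gate >= 0 && reads_per_gate >= 0,
              "cell/read counts must be non-negative")
  assert_that(is_count(replicates) && replicates >= 1,
              "replicates must be a positive integer")
  assert_that(dropout_rate >= 0 && dropout_rate < 1,
              "dropout_rate must be in [0, 1)")
  structure(list(gate_logit_slope = gate_logit_slope,
                 gate_logit_intercept = gate_logit_intercept,
                 cells_per_gate = cells_per_gate,
                 reads_per_gate = reads_per_gate,
                 replicates = as.integer(replicates),
                 dropout_rate = dropout_rate),
            class = "dip_sort_model")
}

#' Simulate gated cell and read counts
#'
#' For each replicate and subpool, cells are allocated to the two gates by a
#' multinomial over variants with weights proportional to the logistic gate
#' probability (high gate) or its complement (low gate), assuming uniform
#' library abundance; sequencing reads are then a single multinomial over the
#' sorted cells of each gate. Dropout zeroes a random subset of non-control
#' variants per replicate after sampling, so total counts after dropout are
#' less than or equal to the configured totals.
#'
#' @param design A `dip_design`.
#' @param truth A `dip_truth` covering all design variants.
#' @param model A `dip_sort_model`.
#' @param seed Integer seed.
#' @return A count table data.frame with columns `position`, `motif_id`,
#'   `gate` ("high"/"low"), `replicate`, `subpool`, `batch`, `count`
#'   (explicit zero rows included).
#' @export
simulate_sort_counts <- function(design, truth, model = sort_model(), seed = 1) {
  stopifnot(inherits(design, "dip_design"), inherits(truth, "dip_truth"),
            inherits(model, "dip_sort_model"))
  v <- design$variants
  f <- truth$fitness[cbind(as.character(v$position), v$motif_id)]
  assert_that(!anyNA(f), "truth must cover all design variants")
  p_high <- stats::plogis(model$gate_logit_slope * f + model$gate_logit_intercept)
  with_seed(seed, {
    out <- vector("list", 2L * model$replicates * length(unique(v$subpool)))
    k <- 0L
    for (r in seq_len(model$replicates)) {
      drop_idx <- integer(0)
      non_ctrl <- which(v$motif_id != design$control_motif_id)
      n_drop <- floor(model$dropout_rate * length(non_ctrl))
      if (n_drop > 0) drop_idx <- sample(non_ctrl, n_drop)
      dropped <- logical(nrow(v)); dropped[drop_idx] <- TRUE
      for (sp in unique(v$subpool)) {
        in_sp <- v$subpool == sp
        for (gate in c("high", "low")) {
          w <- if (gate == "high") p_high[in_sp] else 1 - p_high[in_sp]
          cnt <- integer(sum(in_sp))
          if (sum(w) > 0 && model$cells_per_gate > 0) {
            cells <- stats::rmultinom(1, model$cells_per_gate, w)[, 1]
            if (model$reads_per_gate > 0 && sum(cells) > 0) {
              cnt <- stats::rmultinom(1, model$reads_per_gate, cells)[, 1]
            }
          }
          cnt[dropped[in_sp]] <- 0L
          k <- k + 1L
          out[[k]] <- data.frame(
            position = v$position[in_sp],
            motif_id = v$motif_id[in_sp],
            gate = gate, replicate = r, subpool = sp,
            batch = sprintf("batch%d", r),
            count = as.integer(cnt),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, out)
  })
}

#' Simulate paired junction-spanning reads
#'
#' Emits one read pair per counted read. Each pair is drawn from a fragment
#' of the variant sequence placed so that the first mate spans an insertion
#' junction with at least `flank` matchable nucleotides on each side (the
#' downstream motif/recipient junction is used when the insertion site is too
#' close to the recipient N-terminus). The second mate is the
#' reverse-complemented distal end of the fragment and may or may not span a
#' junction. Read names encode the generating variant
#' (`pos=<i>|motif=<id>|rep=<r>|gate=<g>`), so callers can be scored against
#' ground truth. Substitution errors are uniform at `error_rate` per base.
#'
#' @param design A `dip_design`.
#' @param counts Count table from [simulate_sort_counts()] (or any data.frame
#'   with `position`, `motif_id`, `count` and optional metadata columns).
#' @param read_length Read length in nucleotides (>= 2 * `flank`, >= 30).
#' @param error_rate Per-base substitution probability.
#' @param flank Minimum nucleotides on each side of the anchored junction.
#' @param seed Integer seed.
#' @param fastq Optional length-2 character vector of file paths; when given,
#'   the mates are written as FASTQ (constant quality) to these paths.
#' @return List with `fwd` and `rev`: named character vectors of read
#'   sequences (names are read ids).
#' @export
simulate_reads <- function(design, counts, read_length = 150, error_rate = 0,
                           flank = 15, seed = 1, fastq = NULL) {
  stopifnot(inherits(design, "dip_design"))
  assert_that(read_length >= max(30, 2 * flank),
              "read_length must be at least 2 x flank and >= 30 nt")
  counts <- counts[counts$count > 0, , drop = FALSE]
  n_pairs <- sum(counts$count)
  if (n_pairs == 0) return(list(fwd = character(0), rev = character(0)))
  cds <- design$recipient_cds
  motif_nt <- stats::setNames(design$motifs$nt_seq, design$motifs$motif_id)
  frag_len <- 2L * read_length - 30L

  with_seed(seed, {
    fwd <- character(n_pairs); rev <- character(n_pairs); nm <- character(n_pairs)
    idx <- 0L
    for (row in seq_len(nrow(counts))) {
      p <- counts$position[row]
      m <- counts$motif_id[row]
      cnt <- counts$count[row]
      mnt <- motif_nt[[m]]
      varseq <- paste0(substr(cds, 1, 3 * p), mnt,
                       substr(cds, 3 * p + 1, nchar(cds)))
      vlen <- nchar(varseq)
      j5 <- 3L * p                       # last nt before insert (variant coords)
      j3 <- j5 + nchar(mnt)              # last nt of insert
      # anchor the first mate on a junction with >= flank on each side
      anchor <- if (3L * p >= flank && nchar(mnt) >= flank) j5 else j3
      lo <- max(flank, anchor - vlen + read_length)
      hi <- min(read_length - flank, anchor)
      if (lo > hi) { lo <- hi <- max(flank, min(read_length - flank, anchor)) }
      meta <- paste0(
        "pos=", p, "|motif=", m,
        if (!is.null(counts$replicate)) paste0("|rep=", counts$replicate[row]) else "",
        if (!is.null(counts$gate)) paste0("|gate=", counts$gate[row]) else "")
      for (i in seq_len(cnt)) {
        u <- if (lo < hi) sample(lo:hi, 1L) else lo
        fs <- anchor - u + 1L
        fe <- min(vlen, fs + frag_len - 1L)
        fs <- max(1L, fe - frag_len + 1L)
        frag <- substr(varseq, fs, fe)
        r1 <- substr(frag, 1L, read_length)
        r2 <- fast_revcomp(substr(frag, nchar(frag) - read_length + 1L,
                                  nchar(frag)))
        idx <- idx + 1L
        fwd[idx] <- r1; rev[idx] <- r2
        nm[idx] <- paste0("read", idx, "|", meta)
      }
    }
    if (error_rate > 0) {
      fwd <- add_substitutions(fwd, error_rate)
      rev <- add_substitutions(rev, error_rate)
    }
    names(fwd) <- nm; names(rev) <- nm
    if (!is.null(fastq)) {
      stopifnot(length(fastq) == 2L)
      write_fastq(fwd, fastq[1])
      write_fastq(rev, fastq[2])
    }
    list(fwd = fwd, rev = rev)
  })
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# string-level reverse complement without Biostrings object overhead
fast_revcomp <- function(x) revstr(chartr("ACGT", "TGCA", x))

add_substitutions <- function(reads, rate) {
  bases <- c("A", "C", "G", "T")
  lens <- nchar(reads)
  n_err <- stats::rbinom(length(reads), lens, rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(lens[i], n_err[i])
    s <- strsplit(reads[i], "")[[1]]
    s[pos] <- vapply(s[pos], function(b) sample(setdiff(bases, b), 1), character(1))
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  names(q) <- names(x)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
}

#' Read paired FASTQ files into named sequence vectors
#'
#' @param fastq_fwd,fastq_rev Paths to the mate FASTQ files.
#' @return List with `fwd` and `rev` named character vectors.
#' @export
read_fastq_pairs <- function(fastq_fwd, fastq_rev) {
  rd <- function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq")
    stats::setNames(as.character(x), names(x))
  }
  list(fwd = rd(fastq_fwd), rev = rd(fastq_rev))
}

#' Simulate correlated recipient and motif property tables
#'
#' Builds per-position (recipient) and per-motif biophysical feature tables
#' in which features named in `coupling` carry class- or group-dependent
#' means (plus Gaussian scatter of sd `feature_sd`), while `n_nuisance`
#' additional features per table are independent noise. Optionally one
#' informative feature is duplicated verbatim (pairwise correlation exactly
#' 1) to exercise redundancy reduction downstream.
#'
#' @param design A `dip_design`.
#' @param truth A `dip_truth` providing position classes and motif groups.
#' @param coupling List with `recipient` and `motif` elements; each is a
#'   named list mapping a feature name to a named vector of class/group
#'   means. Empty lists give tables independent of the truth.
#' @param n_nuisance Number of pure-noise features per table.
#' @param feature_sd,nuisance_sd Scatter of informative / nuisance features.
#' @param duplicate_feature Duplicate the first informative recipient
#'   feature as `<name>_dup`?
#' @param seed Integer seed.
#' @return List of class `dip_properties` with `recipient` (data.frame keyed
#'   by `position`) and `motif` (keyed by `motif_id`; includes actual
#'   `length_aa`).
#' @export
simulate_property_tables <- function(
    design, truth,
    coupling = list(
      recipient = list(
        stiffness = c(rigid = 2, intermediate = 0, flexible = -2),
        contact_density = c(rigid = 2.5, intermediate = 1, flexible = -1),
        rmsf = c(rigid = -1.5, intermediate = 0, flexible = 1.5)),
      motif = list(
        hydrophobicity = c(structured = 0, unstructured = -1, hydrophobic = 2),
        negativity = c(structured = 0.5, unstructured = 0, hydrophobic = -0.5))),
    n_nuisance = 6, feature_sd = 0.5, nuisance_sd = 1,
    duplicate_feature = FALSE, seed = 1) {
  stopifnot(inherits(design, "dip_design"), inherits(truth, "dip_truth"))
  L <- design$recipient_length
  ids <- design$motifs$motif_id
  with_seed(seed, {
    rec <- data.frame(position = seq_len(L))
    for (fn in names(coupling$recipient %||% list())) {
      mu <- coupling$recipient[[fn]]
      rec[[fn]] <- mu[truth$position_class] + stats::rnorm(L, 0, feature_sd)
    }
    for (i in seq_len(n_nuisance)) {
      rec[[sprintf("rec_noise_%02d", i)]] <- stats::rnorm(L, 0, nuisance_sd)
    }
    mot <- data.frame(motif_id = ids,
                      length_aa = design$motifs$length_aa,
                      stringsAsFactors = FALSE)
    grp <- truth$motif_group[ids]
    for (fn in names(coupling$motif %||% list())) {
      mu <- coupling$motif[[fn]]
      mot[[fn]] <- mu[grp] + stats::rnorm(length(ids), 0, feature_sd)
    }
    for (i in seq_len(n_nuisance)) {
      mot[[sprintf("motif_noise_%02d", i)]] <- stats::rnorm(length(ids), 0, nuisance_sd)
    }
    if (duplicate_feature && length(names(coupling$recipient %||% list()))) {
      fn <- names(coupling$recipient)[1]
      rec[[paste0(fn, "_dup")]] <- rec[[fn]]
    }
    structure(list(recipient = rec, motif = mot), class = "dip_properties")
  })
}
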