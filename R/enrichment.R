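#' Raw log-ratio enrichment across positions
#'
#' For one (motif, replicate, subpool) group, the per-position raw
#' surface-expression enrichment is the log ratio of pseudocounted read
#' fractions between the high (surface-labelled) and low gates:
#' \deqn{score_i = \ln\frac{0.5+h_i}{\sum_i (0.5+h_i)} -
#'                \ln\frac{0.5+l_i}{\sum_i (0.5+l_i)}}
#' The denominators sum over all positions of the group. Positions lacking
#' reads in either gate are reported as NA (they do not qualify for
#' enrichment); the pseudocounts still include them in the denominators.
#'
#' @param counts_high,counts_low Non-negative integer vectors over the same
#'   positions (names preserved).
#' @param require_both Mask positions that lack reads in either gate
#'   (default TRUE, the dataset rule). Set FALSE to evaluate the bare
#'   formula everywhere.
#' @return Numeric vector of raw scores (NA where masked); all-NA when a
#'   gate has no reads at all.
#' @export
raw_enrichment <- function(counts_high, counts_low, require_both = TRUE) {
  stopifnot(length(counts_high) == length(counts_low))
  assert_that(all(counts_high >= 0) && all(counts_low >= 0),
              "counts must be non-negative")
  th <- sum(0.5 + counts_high)
  tl <- sum(0.5 + counts_low)
  score <- log((0.5 + counts_high) / th) - log((0.5 + counts_low) / tl)
  if (sum(counts_high) == 0 || sum(counts_low) == 0) {
    score[] <- NA_real_
  } else if (require_both) {
    score[counts_high == 0 | counts_low == 0] <- NA_real_
  }
  names(score) <- names(counts_high)
  score
}

#' Poisson standard error of a raw enrichment score
#'
#' \deqn{SE = \sqrt{\frac{1}{c_{high}+0.5} + \frac{1}{c_{low}+0.5} +
#'   \frac{1}{T_{high}+0.5} + \frac{1}{T_{low}+0.5}}}
#' where the totals are the gate sums over positions of the group; the 0.5
#' pseudocount is added once to each term.
#'
#' @param c_high,c_low Per-position gate counts (vectorised).
#' @param total_high,total_low Gate totals for the group.
#' @return Standard error(s), strictly positive.
#' @export
poisson_se <- function(c_high, c_low, total_high, total_low) {
  assert_that(all(c(c_high, c_low, total_high, total_low) >= 0),
              "counts must be non-negative")
  sqrt(1 / (c_high + 0.5) + 1 / (c_low + 0.5) +
       1 / (total_high + 0.5) + 1 / (total_low + 0.5))
}

#' Control-motif anchor statistics
#'
#' Mean and sample standard deviation (ddof = 1) of the flexible-linker
#' control motif's raw enrichment scores across positions within one
#' normalisation scope (collection batch or sequencing subpool).
#'
#' @param control_scores Raw scores of the control motif in scope (NAs
#'   dropped).
#' @param scope Optional scope label stored with the result.
#' @return `dip_control_stats`: list with `mu`, `sigma`, `n`, `scope`.
#' @export
control_stats <- function(control_scores, scope = NA_character_) {
  x <- control_scores[!is.na(control_scores)]
  assert_that(length(x) >= 2,
              "need at least 2 control scores in scope '%s'", scope)
  sigma <- stats::sd(x)
  assert_that(sigma > 0,
              "control scores are constant in scope '%s' (sigma = 0)", scope)
  structure(list(mu = mean(x), sigma = sigma, n = length(x), scope = scope),
            class = "dip_control_stats")
}

#' z-score raw enrichments against the control anchor
#'
#' @param raw Raw score(s).
#' @param stats A `dip_control_stats`.
#' @return `(raw - mu) / sigma`.
#' @export
zscore <- function(raw, stats) {
  stopifnot(inherits(stats, "dip_control_stats"))
  (raw - stats$mu) / stats$sigma
}

# REML estimate of the between-replicate variance M for one variant under
# score_r ~ Normal(theta, M + se_r^2), by Fisher scoring (floored at 0).
reml_between_variance <- function(z, se2, n_iter = 50) {
  n <- length(z)
  if (n < 2) return(0)
  M <- max(0, stats::var(z) - mean(se2))
  for (it in seq_len(n_iter)) {
    w <- 1 / (se2 + M)
    sw <- sum(w)
    theta <- sum(w * z) / sw
    res2 <- (z - theta)^2
    U <- 0.5 * (sum(w^2 * res2) - sum(w) + sum(w^2) / sw)
    I <- 0.5 * (sum(w^2) - 2 * sum(w^3) / sw + (sum(w^2) / sw)^2)
    if (!is.finite(I) || I <= 0) break
    M_new <- M + U / I
    if (M_new < 0) M_new <- 0
    if (abs(M_new - M) < 1e-14 * (1 + M)) { M <- M_new; break }
    M <- M_new
  }
  M
}

#' Combine replicate scores by the REML-weighted average
#'
#' Replicate z-scores of one variant are combined as
#' \deqn{score = \sum_r z_r \frac{\sqrt{M + SE_r^2}}{\sum_r \sqrt{M + SE_r^2}}}
#' where M is the restricted-maximum-likelihood estimate of the
#' between-replicate variance under \eqn{z_r \sim N(\theta, M + SE_r^2)},
#' obtained by Fisher scoring (`n_iter` iterations, floored at 0). The
#' weight expression is implemented exactly as printed; note it up-weights
#' noisier replicates — an inverse-variance alternative
#' (\eqn{w_r \propto 1/(M+SE_r^2)}) is available for sensitivity analysis.
#' Weights are renormalised over the replicates actually present.
#'
#' @param z Replicate z-scores (NAs allowed; dropped).
#' @param se Matching replicate standard errors.
#' @param n_iter Fisher scoring iterations.
#' @param weighting `"as-printed"` (default) or `"inverse-variance"`.
#' @return List with `score`, `M`, `weights` (summing to 1 over contributing
#'   replicates), `n_replicates`; `score = NA` when no replicate is present.
#' @export
reml_combine <- function(z, se, n_iter = 50,
                         weighting = c("as-printed", "inverse-variance")) {
  weighting <- match.arg(weighting)
  stopifnot(length(z) == length(se))
  ok <- !is.na(z) & !is.na(se)
  if (!any(ok)) {
    return(list(score = NA_real_, M = NA_real_, weights = rep(NA_real_, length(z)),
                n_replicates = 0L))
  }
  zz <- z[ok]; ss <- se[ok]
  assert_that(all(ss > 0), "standard errors must be positive")
  M <- reml_between_variance(zz, ss^2, n_iter)
  w_raw <- switch(weighting,
                  "as-printed" = sqrt(M + ss^2),
                  "inverse-variance" = 1 / (M + ss^2))
  w <- w_raw / sum(w_raw)
  weights <- rep(NA_real_, length(z))
  weights[ok] <- w
  list(score = sum(zz * w), M = M, weights = weights,
       n_replicates = sum(ok))
}

#' Filter a fitness matrix by motif completeness
#'
#' Motifs are retained iff their fraction of observed (non-NA) positions is
#' strictly greater than `min_fraction`.
#'
#' @param fitness Positions x motifs matrix with NAs for missing cells.
#' @param min_fraction Completeness threshold (default 0.8).
#' @return The filtered matrix, with attribute `removed_motifs`.
#' @export
filter_dataset <- function(fitness, min_fraction = 0.8) {
  obs <- colMeans(!is.na(fitness))
  keep <- obs > min_fraction
  out <- fitness[, keep, drop = FALSE]
  attr(out, "removed_motifs") <- colnames(fitness)[!keep]
  out
}

#' Score a count table into a combined fitness matrix
#'
#' Full enrichment pipeline: per (motif, replicate, subpool) raw log-ratio
#' enrichment and Poisson standard errors; z-scoring to the flexible-linker
#' control per replicate (with `scope = "global"` the control's scores are
#' pooled across subpools within each replicate/collection batch; with
#' `scope = "subpool"` control statistics are computed per subpool and
#' scores in subpools lacking the control become NA with a warning);
#' REML-weighted combination across replicates; optional motif completeness
#' filter.
#'
#' @param counts Count table (`position`, `motif_id`, `gate`, `replicate`,
#'   `subpool`, `count`; `batch` optional).
#' @param control_motif Identifier of the control motif.
#' @param positions Optional vector of all design positions (defaults to
#'   those present in `counts`).
#' @param scope `"global"` or `"subpool"` control scoping.
#' @param weighting Passed to [reml_combine()].
#' @param min_fraction Motif completeness filter; `NULL` skips filtering.
#' @param n_iter Fisher scoring iterations for the REML step.
#' @return List of class `dip_scores`: `fitness` (positions x motifs
#'   combined-z matrix, NA = missing), `replicate_scores` (long data.frame
#'   with raw, z, se per replicate), `control` (per-scope control stats),
#'   `removed_motifs`.
#' @export
score_counts <- function(counts, control_motif, positions = NULL,
                         scope = c("global", "subpool"),
                         weighting = c("as-printed", "inverse-variance"),
                         min_fraction = 0.8, n_iter = 50) {
  scope <- match.arg(scope)
  weighting <- match.arg(weighting)
  need <- c("position", "motif_id", "gate", "replicate", "subpool", "count")
  assert_that(all(need %in% names(counts)),
              "counts must have columns: %s", paste(need, collapse = ", "))
  assert_that(control_motif %in% counts$motif_id,
              "control motif '%s' absent from counts", control_motif)
  if (is.null(positions)) positions <- sort(unique(counts$position))
  pos_chr <- as.character(positions)

  groups <- unique(counts[, c("motif_id", "replicate", "subpool")])
  long <- vector("list", nrow(groups))
  for (g in seq_len(nrow(groups))) {
    sel <- counts$motif_id == groups$motif_id[g] &
      counts$replicate == groups$replicate[g] &
      counts$subpool == groups$subpool[g]
    sub <- counts[sel, ]
    h <- l <- stats::setNames(rep(0L, length(positions)), pos_chr)
    hh <- sub[sub$gate == "high", ]; ll <- sub[sub$gate == "low", ]
    h[as.character(hh$position)] <- hh$count
    l[as.character(ll$position)] <- ll$count
    raw <- raw_enrichment(h, l)
    se <- poisson_se(h, l, sum(h), sum(l))
    long[[g]] <- data.frame(
      position = positions, motif_id = groups$motif_id[g],
      replicate = groups$replicate[g], subpool = groups$subpool[g],
      count_high = as.integer(h), count_low = as.integer(l),
      raw = as.numeric(raw), se = as.numeric(se),
      stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, long)

  # control anchor per scope; z-scoring
  long$z <- NA_real_
  ctrl_list <- list()
  for (r in unique(long$replicate)) {
    in_r <- long$replicate == r
    if (scope == "global") {
      cs <- control_stats(long$raw[in_r & long$motif_id == control_motif],
                          scope = sprintf("replicate %s", r))
      ctrl_list[[sprintf("rep%s", r)]] <- cs
      long$z[in_r] <- zscore(long$raw[in_r], cs)
    } else {
      for (sp in unique(long$subpool[in_r])) {
        in_sp <- in_r & long$subpool == sp
        craw <- long$raw[in_sp & long$motif_id == control_motif]
        if (sum(!is.na(craw)) < 2) {
          warning(sprintf(
            "no usable control scores in replicate %s subpool %s; scores set NA",
            r, sp))
          next
        }
        cs <- control_stats(craw, scope = sprintf("replicate %s subpool %s", r, sp))
        ctrl_list[[sprintf("rep%s_%s", r, sp)]] <- cs
        long$z[in_sp] <- zscore(long$raw[in_sp], cs)
      }
    }
  }

  # combine replicates per variant
  motifs <- unique(long$motif_id)
  fitness <- matrix(NA_real_, length(positions), length(motifs),
                    dimnames = list(pos_chr, motifs))
  key <- paste(long$position, long$motif_id)
  split_idx <- split(seq_len(nrow(long)), key)
  for (k in names(split_idx)) {
    idx <- split_idx[[k]]
    comb <- reml_combine(long$z[idx], long$se[idx], n_iter = n_iter,
                         weighting = weighting)
    fitness[as.character(long$position[idx[1]]), long$motif_id[idx[1]]] <-
      comb$score
  }
  removed <- character(0)
  if (!is.null(min_fraction)) {
    fitness <- filter_dataset(fitness, min_fraction)
    removed <- attr(fitness, "removed_motifs")
  }
  structure(list(fitness = fitness, replicate_scores = long,
                 control = ctrl_list, removed_motifs = removed,
                 control_motif = control_motif, scope = scope,
                 weighting = weighting),
            class = "dip_scores")
}

#' @export
print.dip_scores <- function(x, ...) {
  cat(sprintf("<dip_scores> %d positions x %d motifs (%d motifs removed by filter)\n",
              nrow(x$fitness), ncol(x$fitness), length(x$removed_motifs)))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * mean(is.na(x$fitness))))
  invisible(x)
}
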