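#' Hierarchically cluster donor motifs by fitness profile
#'
#' Motif insertion profiles (columns of the fitness matrix) are clustered
#' with Ward's method (ward.D2) on a cosine distance computed over
#' pairwise-complete positions. Motifs with fewer than two observed
#' positions are excluded and reported.
#'
#' @param fitness Positions x motifs matrix (NA = missing).
#' @param k Number of groups to cut (default 3: structured / unstructured /
#'   hydrophobic in the reference analysis).
#' @return List with `hclust`, `labels` (named integer vector), `excluded`.
#' @export
cluster_motifs <- function(fitness, k = 3) {
  profiles <- t(fitness)
  obs <- rowSums(!is.na(profiles))
  excluded <- rownames(profiles)[obs < 2]
  profiles <- profiles[obs >= 2, , drop = FALSE]
  assert_that(nrow(profiles) >= 3, "need at least 3 motifs with data")
  d <- cosine_dist(profiles)
  if (anyNA(d)) {
    warning("motif pairs without overlapping positions; distance set to 1")
    d[is.na(d)] <- 1
  }
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  list(hclust = hc, labels = labels, excluded = excluded)
}

#' Export an hclust tree as Newick text
#'
#' @param hc An `hclust` object.
#' @return Newick string (requires the ape package).
#' @export
dendrogram_newick <- function(hc) {
  assert_that(requireNamespace("ape", quietly = TRUE),
              "the ape package is required for Newick export")
  ape::write.tree(ape::as.phylo(hc))
}

# ---- cluster-validity indices (implemented, each voting for a k) ----

within_ss <- function(x, labels) {
  sum(vapply(unique(labels), function(l) {
    xs <- x[labels == l, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }, numeric(1)))
}

silhouette_index <- function(d, labels) {
  n <- nrow(d)
  ks <- unique(labels)
  if (length(ks) < 2) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) sum(d[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(setdiff(ks, labels[i]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

calinski_harabasz_index <- function(x, labels) {
  n <- nrow(x); k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  grand <- colMeans(x)
  b <- sum(vapply(unique(labels), function(l) {
    xs <- x[labels == l, , drop = FALSE]
    nrow(xs) * sum((colMeans(xs) - grand)^2)
  }, numeric(1)))
  w <- within_ss(x, labels)
  (b / (k - 1)) / (w / (n - k))
}

davies_bouldin_index <- function(x, labels) {
  ks <- sort(unique(labels))
  if (length(ks) < 2) return(NA_real_)
  cen <- t(vapply(ks, function(l) colMeans(x[labels == l, , drop = FALSE]),
                  numeric(ncol(x))))
  s <- vapply(seq_along(ks), function(j) {
    xs <- x[labels == ks[j], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xs, 2, cen[j, ])^2)))
  }, numeric(1))
  dm <- as.matrix(stats::dist(cen))
  mean(vapply(seq_along(ks), function(i)
    max(vapply(setdiff(seq_along(ks), i), function(j)
      (s[i] + s[j]) / dm[i, j], numeric(1))), numeric(1)))
}

dunn_index <- function(d, labels) {
  ks <- sort(unique(labels))
  if (length(ks) < 2) return(NA_real_)
  sep <- Inf; diam <- 0
  for (i in seq_along(ks)) {
    in_i <- labels == ks[i]
    diam <- max(diam, max(d[in_i, in_i]))
    for (j in seq_along(ks)) {
      if (j <= i) next
      sep <- min(sep, min(d[in_i, labels == ks[j]]))
    }
  }
  if (diam == 0) return(NA_real_)
  sep / diam
}

# gap statistic: log W_k against uniform references over the bounding box;
# returns the vote per the standard one-standard-error rule
gap_statistic <- function(x, k_range, B = 25, seed = 1, n_starts = 20) {
  n <- nrow(x)
  lw <- function(data, k) {
    km <- stats::kmeans(data, centers = k, nstart = n_starts)
    log(max(km$tot.withinss, .Machine$double.eps))
  }
  rng <- apply(x, 2, range)
  gaps <- sk <- numeric(length(k_range))
  with_seed(seed, {
    for (ki in seq_along(k_range)) {
      k <- k_range[ki]
      obs <- lw(x, k)
      ref <- vapply(seq_len(B), function(b) {
        xb <- apply(rng, 2, function(r) stats::runif(n, r[1], r[2]))
        lw(xb, k)
      }, numeric(1))
      gaps[ki] <- mean(ref) - obs
      sk[ki] <- stats::sd(ref) * sqrt(1 + 1 / B)
    }
  })
  vote <- k_range[length(k_range)]
  for (ki in seq_along(k_range)) {
    if (ki == length(k_range)) { vote <- k_range[ki]; break }
    if (gaps[ki] >= gaps[ki + 1] - sk[ki + 1]) { vote <- k_range[ki]; break }
  }
  list(gap = gaps, se = sk, vote = vote)
}

#' Classify insertion positions from their fitness profiles
#'
#' Positions (rows) are embedded in two dimensions from their motif-response
#' profiles and partitioned by k-means; the number of classes is chosen by
#' majority vote over five cluster-validity indices (silhouette,
#' Calinski--Harabasz, Davies--Bouldin, Dunn, gap statistic), ties broken
#' toward the smaller k. Missing cells are imputed with the per-motif mean
#' before embedding (or high-missingness rows dropped).
#'
#' The default embedding is classical multidimensional scaling of the chosen
#' metric; `embed = "umap"` runs a UMAP embedding (`n_neighbors` local
#' neighbourhood) through the system `python` with the umap-learn package,
#' for users who prefer the nonlinear projection. k-means runs on the 2-D
#' embedding; the validity indices that vote on k are evaluated in the
#' original profile space, so the embedding cannot manufacture structure
#' that is absent from the profiles (the gap statistic, whose reference
#' distribution must match the clustered space, is evaluated on the
#' embedding). The default profile distance is Euclidean: positional classes
#' differ chiefly by additive fitness offsets, which scale-invariant cosine
#' distance discards; cosine remains available via `metric`.
#'
#' @param fitness Positions x motifs matrix with NAs.
#' @param k_range Candidate class numbers (default 2..8).
#' @param n_neighbors UMAP local neighbourhood size (used when
#'   `embed = "umap"`).
#' @param metric `"euclidean"` or `"cosine"` profile distance.
#' @param embed `"mds"` (default) or `"umap"`.
#' @param impute `"motif_mean"` (default) or `"drop"` (drop rows over 50%
#'   missing, impute the rest).
#' @param n_starts k-means restarts.
#' @param gap_B Reference sets for the gap statistic.
#' @param seed Integer seed controlling k-means and the gap references.
#' @return `dip_classes`: list with `labels` (named by position), `k`,
#'   `votes` (per-index k votes), `embedding` (n x 2), `per_k_labels`,
#'   `method` descriptor.
#' @export
position_classes <- function(fitness, k_range = 2:8, n_neighbors = 10,
                             metric = c("euclidean", "cosine"),
                             embed = c("mds", "umap"),
                             impute = c("motif_mean", "drop"),
                             n_starts = 20, gap_B = 25, seed = 1) {
  metric <- match.arg(metric)
  embed <- match.arg(embed)
  impute <- match.arg(impute)
  x <- as.matrix(fitness)
  assert_that(nrow(x) >= n_neighbors + 1,
              "need more positions than n_neighbors")
  if (impute == "drop") {
    keep <- rowMeans(is.na(x)) <= 0.5
    x <- x[keep, , drop = FALSE]
  }
  for (j in seq_len(ncol(x))) {
    mu <- mean(x[, j], na.rm = TRUE)
    if (!is.finite(mu)) mu <- 0
    x[is.na(x[, j]), j] <- mu
  }
  d_prof <- if (metric == "cosine") cosine_dist(x) else euclidean_dist(x)
  emb <- if (embed == "mds") {
    stats::cmdscale(stats::as.dist(d_prof), k = 2)
  } else {
    umap_embed(x, n_neighbors = n_neighbors, metric = metric, seed = seed)
  }
  rownames(emb) <- rownames(x)

  per_k <- list()
  idx <- data.frame(k = k_range, silhouette = NA_real_, calinski = NA_real_,
                    davies_bouldin = NA_real_, dunn = NA_real_)
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    km <- with_seed(seed + k, stats::kmeans(emb, centers = k, nstart = n_starts))
    per_k[[as.character(k)]] <- km$cluster
    idx$silhouette[ki] <- silhouette_index(d_prof, km$cluster)
    idx$calinski[ki] <- calinski_harabasz_index(x, km$cluster)
    idx$davies_bouldin[ki] <- davies_bouldin_index(x, km$cluster)
    idx$dunn[ki] <- dunn_index(d_prof, km$cluster)
  }
  gap <- gap_statistic(emb, k_range, B = gap_B, seed = seed, n_starts = n_starts)
  votes <- c(
    silhouette = k_range[which.max(idx$silhouette)],
    calinski = k_range[which.max(idx$calinski)],
    davies_bouldin = k_range[which.min(idx$davies_bouldin)],
    dunn = k_range[which.max(idx$dunn)],
    gap = gap$vote)
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  k_consensus <- min(winners)
  labels <- per_k[[as.character(k_consensus)]]
  names(labels) <- rownames(x)
  structure(list(labels = labels, k = k_consensus, votes = votes,
                 index_table = idx, gap = gap, embedding = emb,
                 per_k_labels = per_k,
                 method = list(embed = embed, metric = metric,
                               n_neighbors = n_neighbors, seed = seed)),
            class = "dip_classes")
}

# UMAP embedding through the system python (umap-learn); optional backend.
umap_embed <- function(x, n_neighbors = 10, metric = "cosine", seed = 1) {
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.table(x, fin, sep = ",", row.names = FALSE, col.names = FALSE)
  code <- sprintf(paste0(
    "import numpy, umap; x = numpy.loadtxt(%s, delimiter=','); ",
    "e = umap.UMAP(n_neighbors=%d, metric='%s', random_state=%d).fit_transform(x); ",
    "numpy.savetxt(%s, e, delimiter=',')"),
    shQuote(fin), as.integer(n_neighbors), metric, as.integer(seed), shQuote(fout))
  status <- system2("python", c("-c", shQuote(code)))
  assert_that(status == 0 && file.exists(fout),
              "python umap-learn embedding failed (is umap-learn installed?)")
  as.matrix(utils::read.table(fout, sep = ","))
}

#' Per-position correlation profile between motif properties and fitness
#'
#' For every insertion position, the Spearman correlation between each motif
#' property and the fitness of the motifs at that position
#' (pairwise-complete); positions are then clustered on their correlation
#' vectors (cosine distance, Ward linkage) into `k` classes.
#'
#' @param fitness Positions x motifs matrix.
#' @param motif_properties Data.frame keyed by `motif_id` with numeric
#'   property columns.
#' @param min_pairs Minimum complete pairs for a correlation (NA below).
#' @param k Number of position classes to cut.
#' @return List with `rho` (positions x properties), `n` (pair counts),
#'   `classes` (named labels; NA for unclusterable positions), `hclust`.
#' @export
correlation_profile <- function(fitness, motif_properties, min_pairs = 30,
                                k = 3) {
  assert_that("motif_id" %in% names(motif_properties),
              "motif_properties must be keyed by motif_id")
  shared <- intersect(colnames(fitness), motif_properties$motif_id)
  assert_that(length(shared) >= 3, "need at least 3 shared motifs")
  props <- motif_properties[match(shared, motif_properties$motif_id), , drop = FALSE]
  num_cols <- names(props)[vapply(props, is.numeric, logical(1))]
  fm <- fitness[, shared, drop = FALSE]
  rho <- matrix(NA_real_, nrow(fm), length(num_cols),
                dimnames = list(rownames(fm), num_cols))
  npairs <- rho
  for (i in seq_len(nrow(fm))) {
    f <- fm[i, ]
    for (j in seq_along(num_cols)) {
      p <- props[[num_cols[j]]]
      ok <- !is.na(f) & !is.na(p)
      npairs[i, j] <- sum(ok)
      if (sum(ok) >= min_pairs && stats::sd(f[ok]) > 0 && stats::sd(p[ok]) > 0) {
        rho[i, j] <- stats::cor(f[ok], p[ok], method = "spearman")
      }
    }
  }
  obs <- rowSums(!is.na(rho))
  classes <- stats::setNames(rep(NA_integer_, nrow(rho)), rownames(rho))
  hc <- NULL
  usable <- obs >= 2
  if (sum(usable) >= 3) {
    d <- cosine_dist(rho[usable, , drop = FALSE])
    if (anyNA(d)) d[is.na(d)] <- 1
    hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
    classes[usable] <- stats::cutree(hc, k = k)
  }
  list(rho = rho, n = npairs, classes = classes, hclust = hc)
}

#' Class enrichment for an annotated site set
#'
#' Per class, a two-sided Fisher's exact test on the 2 x 2 table of class
#' membership against membership in the annotated site set (e.g.
#' ligand-binding residues). The odds ratio is the sample odds ratio, with
#' Haldane's 0.5 correction applied when any cell is zero.
#'
#' @param labels Named class labels (names are positions).
#' @param sites Vector of positions in the annotated set (subset of the
#'   label names).
#' @return Data.frame with `class`, `n_class`, `n_overlap`, `odds_ratio`,
#'   `p_value`.
#' @export
class_enrichment <- function(labels, sites) {
  assert_that(length(sites) > 0, "site set is empty")
  universe <- names(labels)
  assert_that(!is.null(universe), "labels must be named by position")
  sites <- as.character(sites)
  bad <- setdiff(sites, universe)
  assert_that(length(bad) == 0, "sites outside the position universe: %s",
              paste(utils::head(bad, 5), collapse = ", "))
  in_set <- universe %in% sites
  out <- lapply(sort(unique(labels)), function(cl) {
    in_cl <- labels == cl
    a <- sum(in_cl & in_set); b <- sum(in_cl & !in_set)
    c_ <- sum(!in_cl & in_set); d <- sum(!in_cl & !in_set)
    or <- if (any(c(a, b, c_, d) == 0)) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    } else (a * d) / (b * c_)
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    data.frame(class = cl, n_class = sum(in_cl), n_overlap = a,
               odds_ratio = or, p_value = p)
  })
  do.call(rbind, out)
}

#' Agreement between two categorical labelings
#'
#' Pearson chi-squared test of independence (no continuity correction) and
#' Cramer's V effect size,
#' \eqn{V = \sqrt{\chi^2 / (n (\min(r,c)-1))}}.
#'
#' @param labels_a,labels_b Label vectors over the same entities.
#' @return List with `chisq`, `p_value`, `cramers_v`, `table`.
#' @export
class_agreement <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  assert_that(length(unique(labels_a)) >= 2 && length(unique(labels_b)) >= 2,
              "each labeling needs at least 2 classes")
  tab <- table(labels_a, labels_b)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  v <- sqrt(as.numeric(chi$statistic) / (n * (min(dim(tab)) - 1)))
  list(chisq = as.numeric(chi$statistic), p_value = chi$p.value,
       cramers_v = v, table = tab)
}

#' Terminal versus middle placement of productive insertions
#'
#' Among matrix cells above the productive threshold (restricted to a motif
#' subset), the fraction located in the first or last `terminal_window`
#' recipient positions versus the middle, with the random expectation given
#' by the window sizes.
#'
#' @param fitness Positions x motifs matrix.
#' @param motif_subset Motif ids to consider (default all columns).
#' @param productive_threshold Score above which an insertion counts as
#'   productive (default 0: trafficking better than the flexible-linker
#'   average).
#' @param terminal_window Terminal window size in residues (default 45).
#' @return List with `fractions` (n_term, c_term, middle), `expected`,
#'   `n_productive`.
#' @export
terminal_enrichment <- function(fitness, motif_subset = NULL,
                                productive_threshold = 0,
                                terminal_window = 45) {
  L <- nrow(fitness)
  assert_that(L > 2 * terminal_window,
              "recipient length must exceed 2 x terminal_window")
  if (is.null(motif_subset)) motif_subset <- colnames(fitness)
  fm <- fitness[, intersect(colnames(fitness), motif_subset), drop = FALSE]
  pos <- as.integer(rownames(fitness)) %||% seq_len(L)
  if (anyNA(pos)) pos <- seq_len(L)
  prod <- which(!is.na(fm) & fm > productive_threshold, arr.ind = TRUE)
  assert_that(nrow(prod) > 0, "no productive insertions above threshold")
  p <- pos[prod[, 1]]
  n_term <- mean(p <= terminal_window)
  c_term <- mean(p > L - terminal_window)
  list(fractions = c(n_term = n_term, c_term = c_term,
                     middle = 1 - n_term - c_term),
       expected = c(n_term = terminal_window / L,
                    c_term = terminal_window / L,
                    middle = (L - 2 * terminal_window) / L),
       n_productive = nrow(prod))
}
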