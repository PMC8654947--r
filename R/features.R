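#' Windowed amino-acid scale sums
#'
#' Sums a per-residue scale over sequence windows. For a recipient protein
#' the windows are anchored at each insertion site ("after residue i"):
#' `before` covers residues (i-w+1)..i, `after` covers (i+1)..(i+w), and
#' `centered` covers ceiling(w/2) residues up to and including i plus
#' floor(w/2) after it. For a donor motif the anchors are `whole` (sum over
#' the full sequence), `nterm` (first w residues) and `cterm` (last w
#' residues). Windows clipped at the sequence termini are summed over the
#' available residues and flagged in the `truncated` attribute.
#'
#' @param sequence Amino-acid sequence (one-letter codes).
#' @param scale_name One of `names(aa_scales())`.
#' @param lengths Window lengths (recipient default 1,3,5,7,9,11; motif
#'   terminal windows 1..6).
#' @param anchor One of `"before"`, `"centered"`, `"after"` (per-position
#'   matrix output) or `"whole"`, `"nterm"`, `"cterm"` (single-row output).
#' @param fallback Optional value for residues outside the 20 canonical
#'   amino acids; without it such residues are rejected.
#' @return For positional anchors, an L x length(lengths) matrix (attribute
#'   `truncated`: logical matrix); for motif anchors a named numeric vector.
#' @export
windowed_scale_scores <- function(sequence, scale_name,
                                  lengths = c(1, 3, 5, 7, 9, 11),
                                  anchor = c("before", "centered", "after",
                                             "whole", "nterm", "cterm"),
                                  fallback = NULL) {
  anchor <- match.arg(anchor)
  assert_that(all(lengths >= 1), "window lengths must be positive")
  sc <- scale_table(scale_name)
  res <- strsplit(toupper(sequence), "")[[1]]
  vals <- sc[res]
  if (anyNA(vals)) {
    if (is.null(fallback)) {
      stopf("unknown residue(s): %s (supply fallback= to override)",
            paste(unique(res[is.na(vals)]), collapse = ", "))
    }
    vals[is.na(vals)] <- fallback
  }
  L <- length(vals)
  if (anchor == "whole") {
    return(stats::setNames(sum(vals), sprintf("%s_whole", scale_name)))
  }
  if (anchor %in% c("nterm", "cterm")) {
    out <- vapply(lengths, function(w) {
      idx <- if (anchor == "nterm") seq_len(min(w, L)) else
        seq(max(1L, L - w + 1L), L)
      sum(vals[idx])
    }, numeric(1))
    names(out) <- sprintf("%s_%s_%d", scale_name, anchor, lengths)
    attr(out, "truncated") <- lengths > L
    return(out)
  }
  m <- matrix(NA_real_, L, length(lengths),
              dimnames = list(seq_len(L),
                              sprintf("%s_%s_%d", scale_name, anchor, lengths)))
  trunc <- matrix(FALSE, L, length(lengths), dimnames = dimnames(m))
  for (k in seq_along(lengths)) {
    w <- lengths[k]
    for (i in seq_len(L)) {
      rng <- switch(anchor,
        before = c(i - w + 1L, i),
        after = c(i + 1L, i + w),
        centered = c(i - ceiling(w / 2) + 1L, i + floor(w / 2)))
      lo <- max(1L, rng[1]); hi <- min(L, rng[2])
      trunc[i, k] <- rng[1] < 1L || rng[2] > L || lo > hi
      m[i, k] <- if (lo > hi) 0 else sum(vals[lo:hi])
    }
  }
  attr(m, "truncated") <- trunc
  m
}

#' Recipient per-position sequence features
#'
#' All requested scales summed over before/centered/after windows of the
#' requested lengths at every insertion position.
#'
#' @param sequence Recipient amino-acid sequence.
#' @param scales Scale names (default all 14).
#' @param lengths Window lengths.
#' @param anchors Window anchors.
#' @param fallback Passed to [windowed_scale_scores()].
#' @return Data.frame keyed by `position`.
#' @export
recipient_scale_features <- function(sequence, scales = names(aa_scales()),
                                     lengths = c(1, 3, 5, 7, 9, 11),
                                     anchors = c("before", "centered", "after"),
                                     fallback = NULL) {
  out <- data.frame(position = seq_len(nchar(sequence)))
  for (s in scales) {
    for (a in anchors) {
      m <- windowed_scale_scores(sequence, s, lengths, a, fallback)
      out <- cbind(out, as.data.frame(m))
    }
  }
  out
}

#' Donor motif sequence features
#'
#' Whole-sequence sums plus N-/C-terminal window sums of the requested
#' scales, and motif length.
#'
#' @param sequences Named character vector of motif amino-acid sequences.
#' @param scales Scale names.
#' @param terminal_lengths Terminal window lengths (default 1..6).
#' @param fallback Passed to [windowed_scale_scores()].
#' @return Data.frame keyed by `motif_id` with a `length_aa` column.
#' @export
motif_scale_features <- function(sequences, scales = names(aa_scales()),
                                 terminal_lengths = 1:6, fallback = NULL) {
  assert_that(!is.null(names(sequences)), "sequences must be named")
  rows <- lapply(names(sequences), function(id) {
    sq <- sequences[[id]]
    feats <- c(length_aa = nchar(sq))
    for (s in scales) {
      feats <- c(feats,
                 windowed_scale_scores(sq, s, anchor = "whole"),
                 windowed_scale_scores(sq, s, terminal_lengths, "nterm", fallback),
                 windowed_scale_scores(sq, s, terminal_lengths, "cterm", fallback))
    }
    cbind(data.frame(motif_id = id, stringsAsFactors = FALSE),
          as.data.frame(as.list(feats)))
  })
  do.call(rbind, rows)
}

#' Assemble recipient and motif property tables from multiple sources
#'
#' Merges feature tables keyed by `position` (recipient) or `motif_id`
#' (motif) into one table per side, recording per-column provenance.
#' Sources covering only part of the key universe are rejected with the
#' unmatched keys listed; duplicated feature names across sources are
#' rejected. Absent sides yield tables with the key column only.
#'
#' @param design A `dip_design` defining the position/motif key universes.
#' @param recipient_sources Named list of data.frames keyed by `position`.
#' @param motif_sources Named list of data.frames keyed by `motif_id`.
#' @return `dip_properties`: list with `recipient` and `motif` data.frames;
#'   attribute `provenance` maps each feature column to its source.
#' @export
assemble_feature_table <- function(design, recipient_sources = list(),
                                   motif_sources = list()) {
  stopifnot(inherits(design, "dip_design"))
  merge_side <- function(sources, key, universe) {
    base <- stats::setNames(data.frame(universe, stringsAsFactors = FALSE), key)
    prov <- character(0)
    for (nm in names(sources)) {
      src <- sources[[nm]]
      assert_that(key %in% names(src), "source '%s' lacks key column '%s'",
                  nm, key)
      unmatched <- setdiff(universe, src[[key]])
      assert_that(length(unmatched) == 0,
                  "source '%s' is missing key(s): %s", nm,
                  paste(utils::head(unmatched, 5), collapse = ", "))
      feat_cols <- setdiff(names(src), key)
      dup <- intersect(feat_cols, names(base))
      assert_that(length(dup) == 0,
                  "duplicate feature name(s) across sources: %s",
                  paste(dup, collapse = ", "))
      base <- merge(base, src, by = key, all.x = TRUE, sort = FALSE)
      prov <- c(prov, stats::setNames(rep(nm, length(feat_cols)), feat_cols))
    }
    base <- base[order(match(base[[key]], universe)), , drop = FALSE]
    rownames(base) <- NULL
    attr(base, "provenance") <- prov
    base
  }
  rec <- merge_side(recipient_sources, "position",
                    seq_len(design$recipient_length))
  mot <- merge_side(motif_sources, "motif_id", design$motifs$motif_id)
  structure(list(recipient = rec, motif = mot), class = "dip_properties")
}

#' Merge fitness and property tables into a long model table
#'
#' Builds the long-form (position, motif) table consumed by the
#' compatibility model: one row per observed fitness cell, joined with the
#' recipient features of its position and the motif features of its donor.
#'
#' @param fitness Positions x motifs matrix.
#' @param properties A `dip_properties` (from [simulate_property_tables()]
#'   or [assemble_feature_table()]).
#' @param drop_missing Drop rows with missing fitness (default TRUE).
#' @return Data.frame: `position`, `motif_id`, `fitness`, then recipient and
#'   motif feature columns.
#' @export
merge_long_table <- function(fitness, properties, drop_missing = TRUE) {
  stopifnot(inherits(properties, "dip_properties"))
  long <- data.frame(
    position = rep(as.integer(rownames(fitness)), times = ncol(fitness)),
    motif_id = rep(colnames(fitness), each = nrow(fitness)),
    fitness = as.vector(fitness),
    stringsAsFactors = FALSE)
  if (drop_missing) long <- long[!is.na(long$fitness), , drop = FALSE]
  long <- merge(long, properties$recipient, by = "position")
  long <- merge(long, properties$motif, by = "motif_id")
  long[order(long$position, long$motif_id), ]
}
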