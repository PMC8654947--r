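#' Reference set for junction calling
#'
#' @param recipient_cds Recipient coding sequence (A/C/G/T, length divisible
#'   by 3).
#' @param motif_seqs Named character vector of motif nucleotide sequences.
#' @return A `dip_refs` list.
#' @export
reference_set <- function(recipient_cds, motif_seqs) {
  assert_that(nchar(recipient_cds) %% 3 == 0,
              "recipient CDS length must be divisible by 3")
  assert_that(!is.null(names(motif_seqs)) && all(nzchar(names(motif_seqs))),
              "motif_seqs must be named")
  ok <- grepl("^[ACGT]+$", c(recipient_cds, motif_seqs))
  assert_that(all(ok), "sequences must be over {A,C,G,T}")
  structure(list(recipient_cds = recipient_cds,
                 motif_seqs = motif_seqs,
                 # reversed copies precomputed for suffix-anchored matching
                 rev_cds = revstr(recipient_cds),
                 rev_motifs = vapply(motif_seqs, revstr, character(1))),
            class = "dip_refs")
}

#' @rdname reference_set
#' @param design A `dip_design` to extract references from.
#' @export
design_refs <- function(design) {
  stopifnot(inherits(design, "dip_design"))
  reference_set(design$recipient_cds,
                stats::setNames(design$motifs$nt_seq, design$motifs$motif_id))
}

# longest common prefix length of two strings
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- utf8ToInt(substr(a, 1L, n))
  bv <- utf8ToInt(substr(b, 1L, n))
  neq <- which(av != bv)
  if (length(neq)) neq[1L] - 1L else n
}

revstr <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# match the insert-side segment of a 5'-junction read against the motifs;
# segment may be a motif prefix, or a whole motif followed by recipient
# sequence resuming at junction_nt.
match_motif_prefix <- function(segment, junction_nt, cds, motifs) {
  hits <- character(0)
  for (m in names(motifs)) {
    M <- motifs[[m]]
    if (nchar(segment) <= nchar(M)) {
      if (segment == substr(M, 1L, nchar(segment))) hits <- c(hits, m)
    } else if (substr(segment, 1L, nchar(M)) == M) {
      rest <- substr(segment, nchar(M) + 1L, nchar(segment))
      resume <- substr(cds, junction_nt + 1L, junction_nt + nchar(rest))
      if (rest == resume) hits <- c(hits, m)
    }
  }
  hits
}

# Anchor the read prefix on the recipient CDS by exact seed-and-extend, then
# place the junction. The maximal recipient extension can overrun the true
# junction when the first inserted bases coincide with the recipient
# continuation, so the junction is pulled back (up to `slack` nt) to the
# longest placement at which the intervening segment matches a known motif;
# if no placement matches, the maximal extension is reported with an unknown
# insert. Returns list(status, junction_nt, hits) with junction_nt the
# 0-based CDS offset of the first inserted nucleotide.
anchor_prefix <- function(read, cds, motifs, min_flank, slack = 12L) {
  if (nchar(read) < 2L * min_flank) return(list(status = "too_short"))
  seed <- substr(read, 1L, min_flank)
  hits <- gregexpr(seed, cds, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(list(status = "no_seed"))
  ext <- vapply(as.integer(hits), function(s)
    lcp_len(read, substr(cds, s, nchar(cds))), integer(1))
  best <- max(ext)
  cand <- as.integer(hits)[ext == best]
  if (best == nchar(read)) return(list(status = "no_junction"))
  if (length(unique(cand - 1L + best)) > 1L) return(list(status = "ambiguous"))
  if (best < min_flank) return(list(status = "short_flank"))
  s <- cand[1L]
  for (pl in seq(best, max(min_flank, best - slack), by = -1L)) {
    segment <- substr(read, pl + 1L, nchar(read))
    if (nchar(segment) < min_flank) next
    jn <- s - 1L + pl
    mh <- match_motif_prefix(segment, jn, cds, motifs)
    if (length(mh) == 1L) {
      return(list(status = "ok", junction_nt = jn, hits = mh))
    }
    if (length(mh) > 1L) return(list(status = "ambiguous"))
  }
  if (nchar(read) - best < min_flank) return(list(status = "short_flank"))
  list(status = "ok", junction_nt = s - 1L + best, hits = character(0))
}

#' Call a domain-insertion junction in a single read
#'
#' Simplified DIPseq-style caller: finds the longest exact recipient-matching
#' prefix (or, for reads beginning inside the insert, the recipient-matching
#' suffix), requires at least `min_flank` matchable nucleotides on both sides
#' of the junction, and identifies the intervening segment against the motif
#' references. The insertion site is reported 1-based as "after residue i"
#' (`aa_position = floor(junction_nt / 3)` with `junction_nt` the 0-based CDS
#' offset of the first inserted nucleotide) and `in_frame` is true iff
#' `junction_nt` is a codon boundary. Reads matching only as their reverse
#' complement are called with `direction = "reverse"`. Ambiguous placements
#' (several equally long junctions) are refused rather than guessed; inserts
#' matching no motif are called with `motif_id = "unknown"`.
#'
#' @param read Read sequence (character).
#' @param refs A `dip_refs` reference set.
#' @param min_flank Minimum exact-match flank on each side of the junction.
#' @return A one-row data.frame with columns `aa_position`, `direction`,
#'   `in_frame`, `motif_id`, `status` (`"ok"`, `"ambiguous"`,
#'   `"no_junction"`, or `"no_call"`); non-`"ok"` rows carry NA fields.
#' @export
call_insertion <- function(read, refs, min_flank = 15) {
  stopifnot(inherits(refs, "dip_refs"))
  assert_that(nchar(read) >= 2 * min_flank,
              "read shorter than 2 x min_flank")
  cds <- refs$recipient_cds
  try_one <- function(seqc) {
    res <- anchor_prefix(seqc, cds, refs$motif_seqs, min_flank)
    if (res$status == "ok" && length(res$hits) == 1L) return(res)
    # suffix anchor via reversed space: resolves reads that start inside the
    # insert and motif-identifies reads whose prefix flank is too short
    rres <- anchor_prefix(revstr(seqc), refs$rev_cds, refs$rev_motifs,
                          min_flank)
    if (rres$status == "ok") {
      rres$junction_nt <- nchar(cds) - rres$junction_nt
      if (length(rres$hits) == 1L) return(rres)
    }
    if (res$status == "ok") return(res)
    if (rres$status == "ok") return(rres)
    st <- c(res$status, rres$status)
    list(status = if ("ambiguous" %in% st) "ambiguous"
         else if ("no_junction" %in% st) "no_junction" else st[1])
  }
  result <- NULL
  direction <- NA_character_
  fwd <- try_one(read)
  if (fwd$status == "ok") {
    result <- fwd; direction <- "forward"
  } else {
    rev <- try_one(fast_revcomp(read))
    if (rev$status == "ok") {
      result <- rev; direction <- "reverse"
    } else {
      st <- c(fwd$status, rev$status)
      status <- if ("ambiguous" %in% st) "ambiguous"
                else if ("no_junction" %in% st) "no_junction"
                else "no_call"
      return(data.frame(aa_position = NA_integer_, direction = NA_character_,
                        in_frame = NA, motif_id = NA_character_,
                        status = status, stringsAsFactors = FALSE))
    }
  }
  if (length(result$hits) > 1L) {
    return(data.frame(aa_position = NA_integer_, direction = NA_character_,
                      in_frame = NA, motif_id = NA_character_,
                      status = "ambiguous", stringsAsFactors = FALSE))
  }
  j <- result$junction_nt
  data.frame(
    aa_position = as.integer(j %/% 3L),
    direction = direction,
    in_frame = (j %% 3L) == 0L,
    motif_id = if (length(result$hits) == 1L) unname(result$hits) else "unknown",
    status = "ok", stringsAsFactors = FALSE)
}

#' Reconcile the two mates of a read pair
#'
#' If both mates report an insertion, duplicated calls (same position and
#' motif) are collapsed to one to avoid artificially boosting counts;
#' discordant mates are both dropped. A call on a single mate passes through.
#'
#' @param call_fwd,call_rev One-row call data.frames from [call_insertion()],
#'   or `NULL` / non-"ok" rows for mates without a call.
#' @return A one-row call data.frame, or `NULL` when neither mate called or
#'   both mates called conflicting insertions (discordant pair).
#' @export
dedup_pair <- function(call_fwd, call_rev) {
  f <- is_ok_call(call_fwd); r <- is_ok_call(call_rev)
  if (f && r) {
    if (call_fwd$aa_position == call_rev$aa_position &&
        identical(call_fwd$motif_id, call_rev$motif_id)) {
      return(call_fwd)
    }
    return(NULL)
  }
  if (f) return(call_fwd)
  if (r) return(call_rev)
  NULL
}

is_ok_call <- function(x) {
  !is.null(x) && nrow(x) == 1L && x$status == "ok"
}

#' Call insertions for a set of read pairs
#'
#' Runs [call_insertion()] on both mates of every pair and reconciles them
#' with [dedup_pair()].
#'
#' @param fwd,rev Named character vectors of mate sequences (equal length;
#'   names are read ids).
#' @param refs A `dip_refs`.
#' @param min_flank Minimum junction flank (nt).
#' @param sample Optional sample identifier attached to every call.
#' @return Data.frame of retained calls (`read_id`, `aa_position`,
#'   `direction`, `in_frame`, `motif_id`, and `sample` if given) with a
#'   `stats` attribute counting pairs, ambiguous mates, discordant pairs and
#'   pairs without any call.
#' @export
call_read_pairs <- function(fwd, rev, refs, min_flank = 15, sample = NULL) {
  stopifnot(length(fwd) == length(rev))
  n <- length(fwd)
  out <- vector("list", n)
  ambiguous <- 0L; discordant <- 0L; no_call <- 0L
  ids <- names(fwd) %||% as.character(seq_len(n))
  for (i in seq_len(n)) {
    c1 <- call_insertion(fwd[[i]], refs, min_flank)
    c2 <- call_insertion(rev[[i]], refs, min_flank)
    ambiguous <- ambiguous + sum(c(c1$status, c2$status) == "ambiguous")
    kept <- dedup_pair(c1, c2)
    if (is.null(kept)) {
      if (is_ok_call(c1) && is_ok_call(c2)) discordant <- discordant + 1L
      no_call <- no_call + 1L
      next
    }
    kept$read_id <- ids[i]
    out[[i]] <- kept
  }
  calls <- do.call(rbind, out)
  if (is.null(calls)) {
    calls <- data.frame(aa_position = integer(0), direction = character(0),
                        in_frame = logical(0), motif_id = character(0),
                        status = character(0), read_id = character(0),
                        stringsAsFactors = FALSE)
  }
  if (!is.null(sample)) calls$sample <- sample
  attr(calls, "stats") <- list(n_pairs = n, ambiguous = ambiguous,
                               discordant = discordant, no_call = no_call)
  calls
}

#' Aggregate insertion calls to a count table
#'
#' Counts retained in-frame calls per (position, motif, gate, replicate,
#' subpool, batch); out-of-frame calls are tallied separately (they
#' correspond to frameshifted variants removed by the fluorescence gate in
#' the assay).
#'
#' @param calls Data.frame of calls with a `sample` column (e.g. from
#'   [call_read_pairs()]).
#' @param sample_metadata Data.frame mapping `sample` to `gate`, `replicate`,
#'   `subpool`, `batch`.
#' @return Count table data.frame (`position`, `motif_id`, `gate`,
#'   `replicate`, `subpool`, `batch`, `count`) with attribute
#'   `out_of_frame` (count of discarded out-of-frame calls).
#' @export
aggregate_counts <- function(calls, sample_metadata) {
  need <- c("sample", "gate", "replicate", "subpool", "batch")
  assert_that(all(need %in% names(sample_metadata)),
              "sample_metadata must have columns: %s", paste(need, collapse = ", "))
  if (nrow(calls) == 0) {
    out <- data.frame(position = integer(0), motif_id = character(0),
                      gate = character(0), replicate = integer(0),
                      subpool = character(0), batch = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
    attr(out, "out_of_frame") <- 0L
    return(out)
  }
  assert_that("sample" %in% names(calls), "calls must carry a 'sample' column")
  missing_meta <- setdiff(unique(calls$sample), sample_metadata$sample)
  assert_that(length(missing_meta) == 0,
              "no metadata for sample(s): %s", paste(missing_meta, collapse = ", "))
  oof <- sum(!calls$in_frame)
  keep <- calls[calls$in_frame, , drop = FALSE]
  keep <- merge(keep, sample_metadata, by = "sample")
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(keep))),
    by = keep[, c("aa_position", "motif_id", "gate", "replicate",
                  "subpool", "batch")],
    FUN = sum)
  names(agg)[names(agg) == "aa_position"] <- "position"
  agg <- agg[order(agg$replicate, agg$gate, agg$motif_id, agg$position), ]
  rownames(agg) <- NULL
  attr(agg, "out_of_frame") <- oof
  agg
}

#' Missingness quality control
#'
#' Percent-missing summaries of a fitness matrix (NA cells) or of a count
#' table (a variant is observed when it has reads in at least one gate).
#'
#' @param x A positions x motifs numeric matrix with NAs, or a count table
#'   data.frame with `position`, `motif_id`, `count`.
#' @return List with `per_position`, `per_motif` (named percent vectors in
#'   \[0, 100\]) and `overall`.
#' @export
missingness_qc <- function(x) {
  if (is.data.frame(x)) {
    obs <- stats::aggregate(list(count = x$count),
                            by = list(position = x$position,
                                      motif_id = x$motif_id), FUN = sum)
    m <- stats::xtabs(count ~ position + motif_id, data = obs)
    x <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
    x[m > 0] <- 1
  }
  miss <- is.na(x)
  list(per_position = 100 * rowMeans(miss),
       per_motif = 100 * colMeans(miss),
       overall = 100 * mean(miss))
}
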