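# Alignment-derived sequence profiles: per-column base counts with
# asymmetric pseudocounts, negative-log frequencies, and a persisted
# min-max map onto (-1, 1).

BASES <- c("A", "C", "G", "U")

# IUPAC ambiguity codes -> compatible bases (fractional counts).
iupac_sets <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("G", "C"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

#' Pseudocount settings for the alignment profile
#'
#' The correction added to observed per-column base counts before taking
#' frequencies: a large bonus for the query's own base and a small floor for
#' the other three, preventing zero frequencies.
#'
#' @param s_query Added to the query base's count (default 9.0).
#' @param s_other Added to each other base's count (default 0.3).
#' @return List of class `pseudocount_config`.
#' @export
pseudocount_config <- function(s_query = 9.0, s_other = 0.3) {
  if (s_query < 0 || s_other < 0) {
    stop("pseudocounts must be non-negative", call. = FALSE)
  }
  structure(list(s_query = s_query, s_other = s_other),
            class = "pseudocount_config")
}

#' Per-column base counts of an alignment
#'
#' Counts base occurrences at each query position over all alignment rows
#' (query row included). Gaps contribute to no base; IUPAC ambiguity codes
#' contribute fractional counts split equally among their compatible bases.
#' T is mapped to U on input. Columns where the query itself has a gap are
#' dropped, so positions are in query coordinates.
#'
#' @param alignment Character vector of aligned sequences, query first, all
#'   the same length (as from an aligned FASTA).
#' @return A tibble with columns `position` (0-based, query coordinates),
#'   `query_base`, `nA`, `nC`, `nG`, `nU`.
#' @export
#' @examples
#' count_alignment_columns(c("ACGU", "ACGA", "AG-U"))
count_alignment_columns <- function(alignment) {
  stopifnot(is.character(alignment), length(alignment) >= 1)
  alignment <- gsub("T", "U", toupper(alignment), fixed = TRUE)
  L <- nchar(alignment[1])
  if (any(nchar(alignment) != L)) {
    stop("alignment rows differ in length", call. = FALSE)
  }
  rows <- strsplit(alignment, "", fixed = TRUE)
  query <- rows[[1]]
  keep <- which(!query %in% c("-", "."))

  counts <- matrix(0, nrow = length(keep), ncol = 4,
                   dimnames = list(NULL, BASES))
  for (row in rows) {
    ch <- row[keep]
    for (k in seq_along(ch)) {
      set <- iupac_sets[[ch[k]]]
      if (!is.null(set)) {
        counts[k, set] <- counts[k, set] + 1 / length(set)
      }
    }
  }
  tibble::tibble(
    position = seq_along(keep) - 1L,
    query_base = query[keep],
    nA = unname(counts[, "A"]), nC = unname(counts[, "C"]),
    nG = unname(counts[, "G"]), nU = unname(counts[, "U"])
  )
}

#' Add pseudocounts to alignment counts
#'
#' Adds `s_query` to the count of the query's own base at each position and
#' `s_other` to the other bases. A query base outside A/C/G/U (ambiguity
#' code, unknown) gets the uniform `s_other` on all four bases, with no
#' query bonus.
#'
#' @param counts Tibble from [count_alignment_columns()] (columns
#'   `query_base`, `nA`..`nU`).
#' @param cfg A [pseudocount_config()].
#' @return The tibble with corrected `nA`..`nU`.
#' @export
apply_pseudocounts <- function(counts, cfg = pseudocount_config()) {
  stopifnot(all(c("query_base", "nA", "nC", "nG", "nU") %in% names(counts)))
  m <- as.matrix(counts[, c("nA", "nC", "nG", "nU")])
  if (any(m < 0)) stop("negative counts", call. = FALSE)
  colnames(m) <- BASES
  m <- m + cfg$s_other
  idx <- match(counts$query_base, BASES)
  known <- !is.na(idx)
  m[cbind(which(known), idx[known])] <-
    m[cbind(which(known), idx[known])] - cfg$s_other + cfg$s_query
  out <- counts
  out$nA <- unname(m[, "A"]); out$nC <- unname(m[, "C"])
  out$nG <- unname(m[, "G"]); out$nU <- unname(m[, "U"])
  out
}

#' Convert corrected counts to a negative-log-frequency profile
#'
#' P\[i,j\] = -log(N\[i,j\] / sum_j N\[i,j\]), natural log. The implied
#' per-column frequencies exp(-P) always sum to 1.
#'
#' @param counts Tibble with `nA`..`nU`, every column sum positive.
#' @return Tibble with `position`, `query_base`, and raw profile columns
#'   `pA`, `pC`, `pG`, `pU`.
#' @export
counts_to_profile <- function(counts) {
  m <- as.matrix(counts[, c("nA", "nC", "nG", "nU")])
  rs <- rowSums(m)
  if (any(rs <= 0)) stop("zero column sum; apply pseudocounts first", call. = FALSE)
  p <- -log(m / rs)
  tibble::tibble(
    position = counts$position,
    query_base = counts$query_base,
    pA = unname(p[, 1]), pC = unname(p[, 2]),
    pG = unname(p[, 3]), pU = unname(p[, 4])
  )
}

#' Map raw profile values onto (-1, 1)
#'
#' Global min-max affine map. At training time bounds are taken from the
#' data and returned for persistence with the model; at prediction time the
#' stored bounds are supplied and out-of-range values are clamped.
#'
#' @param profile Tibble from [counts_to_profile()].
#' @param bounds Optional `c(p_lo, p_hi)` from training.
#' @return List: `profile` (tibble with added `normA`..`normU`) and `bounds`.
#' @export
normalize_profile <- function(profile, bounds = NULL) {
  raw <- as.matrix(profile[, c("pA", "pC", "pG", "pU")])
  if (is.null(bounds)) bounds <- c(min(raw), max(raw))
  p_lo <- bounds[1]; p_hi <- bounds[2]
  if (p_hi == p_lo) {
    warning("degenerate profile bounds; normalized values set to 0", call. = FALSE)
    nm <- raw * 0
  } else {
    nm <- 2 * (raw - p_lo) / (p_hi - p_lo) - 1
    nm[nm > 1] <- 1
    nm[nm < -1] <- -1
  }
  out <- profile
  out$normA <- unname(nm[, 1]); out$normC <- unname(nm[, 2])
  out$normG <- unname(nm[, 3]); out$normU <- unname(nm[, 4])
  list(profile = out, bounds = c(p_lo = unname(p_lo), p_hi = unname(p_hi)))
}

#' Build a normalized profile from an alignment in one call
#'
#' @inheritParams count_alignment_columns
#' @inheritParams apply_pseudocounts
#' @inheritParams normalize_profile
#' @return As [normalize_profile()].
#' @export
sequence_profile <- function(alignment, cfg = pseudocount_config(),
                             bounds = NULL) {
  alignment |>
    count_alignment_columns() |>
    apply_pseudocounts(cfg) |>
    counts_to_profile() |>
    normalize_profile(bounds)
}

#' Read a pre-computed counts TSV
#'
#' Expected columns: `position`, `query_base`, `nA`, `nC`, `nG`, `nU` — the
#' tabular alternative to an aligned FASTA for profile construction.
#'
#' @param path TSV file.
#' @return Counts tibble as from [count_alignment_columns()].
#' @export
read_counts_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("position", "query_base", "nA", "nC", "nG", "nU")
  if (!all(need %in% names(x))) {
    stop("counts TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(x[, need])
}
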