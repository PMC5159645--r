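# Windowed feature encoding: per-position vectors concatenated over a
# symmetric window, padded with (-1, ..., -1) past the sequence ends.

#' One-hot encode an RNA sequence
#'
#' Each position becomes a 4-vector in fixed A, C, G, U order with +1 at the
#' query base and -1 elsewhere. Bases outside A/C/G/U reuse the padding
#' vector (-1,-1,-1,-1), keeping the feature alphabet closed. T is mapped to
#' U on input.
#'
#' @param sequence A single character string over A/C/G/U/T/N.
#' @return Numeric matrix, one row per position, 4 columns named A, C, G, U.
#' @export
#' @examples
#' encode_onehot("ACGU")
encode_onehot <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- gsub("T", "U", toupper(sequence), fixed = TRUE)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(ch) == 0) stop("empty sequence", call. = FALSE)
  m <- matrix(-1, nrow = length(ch), ncol = 4, dimnames = list(NULL, BASES))
  idx <- match(ch, BASES)
  known <- !is.na(idx)
  m[cbind(which(known), idx[known])] <- 1
  m
}

#' Profile tibble to per-position vector matrix
#'
#' Extracts the normalized profile columns as the 4-vector-per-position
#' matrix the window encoder consumes.
#'
#' @param profile Normalized profile tibble (with `normA`..`normU`), e.g.
#'   `sequence_profile(aln)$profile`.
#' @return Numeric matrix, one row per position.
#' @export
encode_profile <- function(profile) {
  stopifnot(all(c("normA", "normC", "normG", "normU") %in% names(profile)))
  m <- as.matrix(profile[, c("normA", "normC", "normG", "normU")])
  colnames(m) <- BASES
  m
}

#' Windowed feature rows
#'
#' The feature row for position i is the concatenation of the per-position
#' vectors at i-w ... i+w in order; indices falling outside the sequence are
#' replaced by the padding vector (all -1). Row dimension is therefore
#' A x (2w + 1) for alphabet size A, regardless of sequence length — 324 for
#' the 4-letter RNA alphabet at w = 40, and 340 for a 20-letter protein
#' alphabet at w = 8.
#'
#' @param vectors Per-position matrix (rows = positions, columns = alphabet),
#'   from [encode_onehot()] or [encode_profile()].
#' @param w Non-negative integer half-window (default 40).
#' @param pad_value Scalar filling out-of-range positions (default -1).
#' @return Numeric matrix with `nrow(vectors)` rows and
#'   `ncol(vectors) * (2w + 1)` columns.
#' @export
#' @examples
#' dim(window_features(encode_onehot("ACGU"), w = 40))  # 4 x 324
window_features <- function(vectors, w = 40, pad_value = -1) {
  stopifnot(is.matrix(vectors), nrow(vectors) >= 1)
  if (!is.numeric(w) || w < 0 || w != floor(w)) {
    stop("`w` must be a non-negative integer", call. = FALSE)
  }
  L <- nrow(vectors)
  A <- ncol(vectors)
  padded <- rbind(
    matrix(pad_value, nrow = w, ncol = A),
    vectors,
    matrix(pad_value, nrow = w, ncol = A)
  )
  blocks <- lapply(0:(2 * w), function(off) padded[(1 + off):(L + off), , drop = FALSE])
  out <- do.call(cbind, blocks)
  dimnames(out) <- NULL
  out
}

#' Encode a set of chains into one feature matrix with provenance
#'
#' @param chains Named list of per-chain inputs: character sequences
#'   (`mode = "seq"`) or normalized profile tibbles (`mode = "prof"`).
#' @param mode `"seq"` or `"prof"`.
#' @param w Half-window; see [window_features()].
#' @return List: `features` (matrix), `provenance` (tibble `chain`,
#'   `position`).
#' @export
encode_chains <- function(chains, mode = c("seq", "prof"), w = 40) {
  mode <- match.arg(mode)
  stopifnot(length(chains) >= 1, !is.null(names(chains)))
  per <- purrr::map(chains, function(x) {
    v <- if (mode == "seq") encode_onehot(x) else encode_profile(x)
    window_features(v, w = w)
  })
  prov <- purrr::imap(per, function(m, id) {
    tibble::tibble(chain = id, position = seq_len(nrow(m)) - 1L)
  }) |> purrr::list_rbind()
  list(features = do.call(rbind, per), provenance = prov)
}
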