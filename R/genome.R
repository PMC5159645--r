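# Downstream genome analyses: DMS reactivity normalization against a
# denatured control, minor-allele-frequency bin association, and
# transcript-boundary ASA profiles.

#' Normalize DMS reactivity against the denatured control
#'
#' Per mRNA, in order: (1) divide each condition's raw read counts by that
#' condition's maximum (removing abundance effects); (2) average each
#' condition over consecutive nonoverlapping fragments of `fragment` bases,
#' dropping a final partial fragment; (3) drop fragments whose denatured or
#' compared fragment mean is zero; (4) report the compare/denature ratio per
#' surviving fragment, removing position-dependent systematic bias.
#'
#' @param track Data frame with per-base counts: columns `position`,
#'   `denature`, and the condition named by `compare` (e.g. `vivo`,
#'   `invitro`); one mRNA per call, or use a grouped pipeline.
#' @param compare Name of the condition column to normalize.
#' @param fragment Fragment length in bases (default 50).
#' @return Tibble `fragment_index` (0-based), `denature_mean`,
#'   `compare_mean` (max-normalized fragment means) and `reactivity`
#'   (their ratio), surviving fragments only.
#' @export
normalize_dms <- function(track, compare = "vivo", fragment = 50) {
  stopifnot(is.data.frame(track), "denature" %in% names(track),
            compare %in% names(track))
  den <- track$denature
  cmp <- track[[compare]]
  if (any(den < 0) || any(cmp < 0)) stop("negative read count", call. = FALSE)
  if (max(den) == 0 || max(cmp) == 0) {
    stop("zero maximum read in '", if (max(den) == 0) "denature" else compare,
         "'", call. = FALSE)
  }
  den <- den / max(den)
  cmp <- cmp / max(cmp)

  n_frag <- length(den) %/% fragment
  if (n_frag == 0) {
    warning("track shorter than one fragment; empty result", call. = FALSE)
    return(tibble::tibble(fragment_index = integer(), denature_mean = numeric(),
                          compare_mean = numeric(), reactivity = numeric()))
  }
  idx <- rep(seq_len(n_frag), each = fragment)
  used <- seq_len(n_frag * fragment)
  dm <- as.numeric(tapply(den[used], idx, mean))
  cm <- as.numeric(tapply(cmp[used], idx, mean))
  keep <- dm > 0 & cm > 0
  if (!any(keep)) warning("all fragments dropped (null counts)", call. = FALSE)
  tibble::tibble(
    fragment_index = as.integer(which(keep)) - 1L,
    denature_mean = dm[keep],
    compare_mean = cm[keep],
    reactivity = cm[keep] / dm[keep]
  )
}

#' Filter mRNA tracks by reacted-base count
#'
#' Keeps tracks with at least `min_reacted` positions showing a nonzero
#' count in the compared condition.
#'
#' @param tracks Data frame of per-base counts with an `mrna_id` column.
#' @param compare Condition column checked for reacted bases.
#' @param min_reacted Minimum number of nonzero positions (default 4000).
#' @return The filtered tibble.
#' @export
filter_dms_tracks <- function(tracks, compare = "vivo", min_reacted = 4000) {
  stopifnot(all(c("mrna_id", compare) %in% names(tracks)))
  tracks |>
    dplyr::group_by(.data$mrna_id) |>
    dplyr::filter(sum(.data[[compare]] > 0) >= min_reacted) |>
    dplyr::ungroup()
}

#' Bin SNVs by predicted ASA and correlate bin means with log MAF
#'
#' Records are stably sorted by predicted value and split into `n_bins`
#' near-equal bins (the first `n %% n_bins` bins take one extra record).
#' Within each bin the mean predicted value and the mean log10 minor allele
#' frequency are computed; the returned correlation is the Pearson r over
#' the bin means.
#'
#' @param snvs Data frame with columns `predicted` and `maf`; rows with
#'   `maf <= 0` are rejected (their count is reported in a message).
#' @param n_bins Number of bins (default 100).
#' @return List of class `rnasa_maf`: `bins` (tibble `bin`, `n`,
#'   `mean_pred`, `mean_log_maf`), `r`, `n_used`, `n_rejected`.
#' @export
bin_association <- function(snvs, n_bins = 100) {
  stopifnot(all(c("predicted", "maf") %in% names(snvs)))
  bad <- !is.finite(snvs$maf) | snvs$maf <= 0 | !is.finite(snvs$predicted)
  if (any(bad)) {
    message(sum(bad), " record(s) with non-positive MAF or non-finite values rejected")
    snvs <- snvs[!bad, , drop = FALSE]
  }
  n <- nrow(snvs)
  if (n < n_bins) {
    stop("need at least ", n_bins, " SNVs, got ", n, call. = FALSE)
  }
  ord <- order(snvs$predicted)                      # stable: ties keep input order
  base_size <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base_size, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bin <- rep(seq_len(n_bins), times = sizes)

  bins <- tibble::tibble(
    bin = bin,
    predicted = snvs$predicted[ord],
    log_maf = log10(snvs$maf[ord])
  ) |>
    dplyr::group_by(bin = .data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_pred = mean(.data$predicted),
      mean_log_maf = mean(.data$log_maf),
      .groups = "drop"
    )
  structure(
    list(
      bins = bins,
      r = pearson_r(bins$mean_pred, bins$mean_log_maf),
      n_used = n,
      n_rejected = sum(bad)
    ),
    class = "rnasa_maf"
  )
}

#' @export
print.rnasa_maf <- function(x, ...) {
  cat("<rnasa_maf> ", nrow(x$bins), " bins over ", x$n_used, " SNVs\n", sep = "")
  cat("  bin-mean Pearson r:", round(x$r, 3), "\n")
  invisible(x)
}

#' @export
tidy.rnasa_maf <- function(x, ...) x$bins

#' @export
glance.rnasa_maf <- function(x, ...) {
  tibble::tibble(n_bins = nrow(x$bins), n_used = x$n_used,
                 n_rejected = x$n_rejected, r = x$r)
}

#' Bin association within strata
#'
#' Applies [bin_association()] independently per stratum (region class or
#' mutation type). Strata smaller than `n_bins` records cannot be binned
#' and are skipped with a warning, never silently merged.
#'
#' @param snvs Data frame with `predicted`, `maf`, and the stratum column.
#' @param stratum Name of the stratifying column (default `"region"`).
#' @param n_bins Bins per stratum (default 100).
#' @return Tibble `stratum`, `n`, `r` (NA for skipped strata).
#' @export
stratified_bin_association <- function(snvs, stratum = "region", n_bins = 100) {
  stopifnot(stratum %in% names(snvs))
  snvs |>
    dplyr::group_by(stratum = .data[[stratum]]) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < n_bins) {
        warning("stratum '", key$stratum, "' has ", nrow(d),
                " records (< ", n_bins, "); skipped", call. = FALSE)
        return(tibble::tibble(n = nrow(d), r = NA_real_))
      }
      ba <- bin_association(d, n_bins = n_bins)
      tibble::tibble(n = ba$n_used, r = ba$r)
    }) |>
    dplyr::ungroup()
}

#' Mean ASA profile around transcript region boundaries
#'
#' For each boundary type (5'UTR|CDS, CDS|intron, intron|CDS, CDS|3'UTR)
#' and each offset -flank ... flank-1 relative to the boundary line (offset
#' 0 is the first base downstream of the line), averages predicted ASA over
#' transcripts. Transcripts whose 5'UTR, CDS, intron or 3'UTR totals fall
#' below `min_region` bases are excluded and counted.
#'
#' @param transcripts List of transcripts; each a list with `asa` (per-base
#'   numeric) and `regions`, a data frame `region`, `start`, `end` (0-based,
#'   half-open, ordered) labelling every base as one of `five_utr`, `cds`,
#'   `intron`, `three_utr`.
#' @param flank Bases averaged on each side of a boundary (default 50).
#' @param min_region Minimum total bases per region class (default 100).
#' @return List of class `rnasa_boundary`: `profile` (tibble `boundary`,
#'   `offset`, `mean_asa`, `n`), `n_used`, `n_excluded`.
#' @export
boundary_profile <- function(transcripts, flank = 50, min_region = 100) {
  region_levels <- c("five_utr", "cds", "intron", "three_utr")
  boundary_name <- function(a, b) paste(a, b, sep = "|")

  per_tx <- purrr::map(transcripts, function(tx) {
    reg <- tx$regions
    stopifnot(all(reg$region %in% region_levels),
              all(reg$start < reg$end),
              all(diff(reg$start) > 0),
              max(reg$end) <= length(tx$asa))
    totals <- tapply(reg$end - reg$start, reg$region, sum)
    if (any(is.na(totals[region_levels])) || any(totals[region_levels] < min_region)) {
      return(NULL)
    }
    bounds <- tibble::tibble(
      boundary = boundary_name(reg$region[-nrow(reg)], reg$region[-1]),
      at = reg$end[-nrow(reg)]
    )
    purrr::pmap(bounds, function(boundary, at) {
      pos <- (at - flank):(at + flank - 1)
      ok <- pos >= 0 & pos < length(tx$asa)
      tibble::tibble(
        boundary = boundary,
        offset = (pos - at)[ok],
        asa = tx$asa[pos[ok] + 1]
      )
    }) |> purrr::list_rbind()
  })
  excluded <- sum(vapply(per_tx, is.null, logical(1)))
  rows <- purrr::list_rbind(purrr::compact(per_tx))
  if (nrow(rows) == 0) stop("no transcript passed the region-length filter",
                            call. = FALSE)
  profile <- rows |>
    dplyr::group_by(boundary = .data$boundary, offset = .data$offset) |>
    dplyr::summarise(mean_asa = mean(.data$asa), n = dplyr::n(), .groups = "drop")
  structure(
    list(profile = profile,
         n_used = length(per_tx) - excluded,
         n_excluded = excluded),
    class = "rnasa_boundary"
  )
}

#' @export
print.rnasa_boundary <- function(x, ...) {
  cat("<rnasa_boundary> ", x$n_used, " transcript(s), ",
      length(unique(x$profile$boundary)), " boundary type(s)\n", sep = "")
  invisible(x)
}

#' @export
tidy.rnasa_boundary <- function(x, ...) x$profile
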