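# Synthetic fixtures with planted, recoverable structure: toy coordinate
# sets, mutated-homolog alignments, SNV tables with a planted ASA-MAF link,
# and DMS read tracks with a planted in-vivo signal. Every generator is
# fully determined by its seed and writes/returns the same shapes the real
# adapters produce, so tests exercise the true pipeline paths.

# Reduced heavy-atom inventories (8 named atoms per base): enough to
# exercise ASA aggregation and the completeness filter without full
# nucleotide chemistry.
fixture_inventory <- function() {
  list(
    A = c("P", "O5'", "C4'", "C1'", "N9", "C8", "N1", "C2"),
    C = c("P", "O5'", "C4'", "C1'", "N1", "C2", "N3", "C4"),
    G = c("P", "O5'", "C4'", "C1'", "N9", "C8", "O6", "C2"),
    U = c("P", "O5'", "C4'", "C1'", "N1", "C2", "O4", "C5")
  )
}

random_rna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Synthetic RNA chain with 3D coordinates
#'
#' Places residues along a loose helix with small per-atom jitter, using the
#' reduced 8-atom inventories of [fixture_inventory()]. The layout is
#' sterically plausible (minimum pairwise heavy-atom distance >= 1.5
#' Angstrom, enforced with bounded retries). Atoms can be deleted to
#' exercise the completeness filter.
#'
#' @param seed Integer; fully determines the output.
#' @param n_residues Chain length (default 12).
#' @param delete Optional tibble/data.frame with columns `residue_index`
#'   (0-based) and `atom_name` naming atoms to remove.
#' @param min_dist Minimum allowed pairwise atom distance (default 1.5).
#' @return List: `atoms` (tibble as read_rna_structure produces),
#'   `sequence`, `inventory`.
#' @export
make_synthetic_chain <- function(seed, n_residues = 12, delete = NULL,
                                 min_dist = 1.5) {
  inv <- fixture_inventory()
  withr::with_seed(seed, {
    seq_ch <- sample(BASES, n_residues, replace = TRUE)
    for (attempt in 1:50) {
      rows <- purrr::imap(seq_ch, function(b, i) {
        t <- (i - 1) * 0.6
        center <- c(7 * cos(t), 7 * sin(t), 2.8 * (i - 1))
        names_i <- inv[[b]]
        k <- length(names_i)
        ang <- 2 * pi * (seq_len(k) - 1) / k + stats::runif(1, 0, 2 * pi)
        tibble::tibble(
          atom_name = names_i,
          element = substr(gsub("[^A-Z]", "", names_i), 1, 1),
          x = center[1] + 2.4 * cos(ang) + stats::rnorm(k, 0, 0.1),
          y = center[2] + 2.4 * sin(ang) + stats::rnorm(k, 0, 0.1),
          z = center[3] + stats::rnorm(k, 0, 0.25),
          residue_index = i - 1L,
          residue_base = b
        )
      }) |> purrr::list_rbind()
      if (min(stats::dist(as.matrix(rows[, c("x", "y", "z")]))) >= min_dist) break
      if (attempt == 50) stop("could not satisfy atom spacing", call. = FALSE)
    }
  })
  rows$vdw_radius <- unname(vdw_radii()[rows$element])
  if (!is.null(delete)) {
    rows <- dplyr::anti_join(rows, tibble::as_tibble(delete),
                             by = c("residue_index", "atom_name"))
  }
  list(atoms = rows, sequence = paste(seq_ch, collapse = ""),
       inventory = inv)
}

#' Regression fixture: chains with a planted window-local signal
#'
#' Targets are a fixed random linear map of the one-hot window of half-width
#' `h` around each position, plus Gaussian noise, clipped to \[0, 1\] — a
#' recoverable stand-in for structure-derived normalized ASA. The linear map
#' is drawn once from the seed, so an encoder window covering `h` can
#' recover the signal while chain-level cross-validation measures held-out
#' generalization.
#'
#' @param seed Integer seed.
#' @param n_chains Number of chains (default 60).
#' @param len_range Chain length range, inclusive (default c(50, 70)).
#' @param h Planted dependency half-width (default 3); keep below the
#'   encoder window.
#' @param noise_sd Gaussian noise SD on the target scale (default 0.08).
#' @param signal_sd SD of the noise-free planted signal (default 0.18).
#' @return Tibble `chain`, `position`, `base`, `target`, plus attribute
#'   `coefficients` (the planted map).
#' @export
make_asa_regression_set <- function(seed, n_chains = 60,
                                    len_range = c(50, 70), h = 3,
                                    noise_sd = 0.08, signal_sd = 0.18) {
  withr::with_seed(seed, {
    coefs <- stats::rnorm(4 * (2 * h + 1))
    chains <- purrr::map(seq_len(n_chains), function(i) {
      L <- sample(len_range[1]:len_range[2], 1)
      s <- random_rna(L)
      feat <- window_features(encode_onehot(s), w = h)
      raw <- as.numeric(feat %*% coefs)
      raw <- (raw - mean(raw)) / stats::sd(raw) * signal_sd
      target <- pmin(1, pmax(0, 0.5 + raw + stats::rnorm(L, 0, noise_sd)))
      tibble::tibble(
        chain = sprintf("chain%03d", i),
        position = seq_len(L) - 1L,
        base = strsplit(s, "")[[1]],
        target = target
      )
    }) |> purrr::list_rbind()
  })
  attr(chains, "coefficients") <- coefs
  attr(chains, "h") <- h
  chains
}

#' Synthetic multiple alignment of mutated homologs
#'
#' Homologs are the query with i.i.d. per-base substitutions at
#' `mutation_rate` and occasional gaps; columns flagged `conserved` get
#' substitution (and gap) rate zero, planting a conservation signal the
#' profile can detect.
#'
#' @param query RNA sequence (string over ACGU).
#' @param seed Integer seed.
#' @param n_homologs Number of homolog rows beyond the query (default 30).
#' @param mutation_rate Per-base substitution probability (default 0.3).
#' @param gap_rate Per-base gap probability in homologs (default 0.02).
#' @param conserved Logical vector, length nchar(query); `TRUE` columns are
#'   never mutated. Default none.
#' @return Character vector of aligned rows, query first.
#' @export
make_synthetic_alignment <- function(query, seed, n_homologs = 30,
                                     mutation_rate = 0.3, gap_rate = 0.02,
                                     conserved = NULL) {
  q <- strsplit(toupper(query), "")[[1]]
  stopifnot(all(q %in% BASES))
  L <- length(q)
  if (is.null(conserved)) conserved <- rep(FALSE, L)
  stopifnot(length(conserved) == L)
  withr::with_seed(seed, {
    homologs <- purrr::map_chr(seq_len(n_homologs), function(i) {
      row <- q
      mutable <- which(!conserved)
      mut <- mutable[stats::runif(length(mutable)) < mutation_rate]
      row[mut] <- vapply(row[mut], function(b) sample(setdiff(BASES, b), 1),
                         character(1))
      gap <- mutable[stats::runif(length(mutable)) < gap_rate]
      row[gap] <- "-"
      paste(row, collapse = "")
    })
  })
  c(query, homologs)
}

#' Fixture linking conservation to the regression target
#'
#' Builds chains whose targets combine a base-identity effect (visible to
#' one-hot encoding) with a buriedness effect tied to planted conservation:
#' buried (low-target) positions are conserved across homologs, exposed
#' positions mutate freely. Profile-based encoding can therefore read the
#' buriedness signal that sequence-only encoding cannot.
#'
#' @param seed Integer seed.
#' @param n_chains Number of chains (default 24).
#' @param len Chain length (default 60).
#' @param n_homologs Homologs per chain (default 40).
#' @param base_effect SD of the base-identity target component (default 0.05).
#' @param burial_effect Target gap between buried and exposed positions
#'   (default 0.35).
#' @param noise_sd Gaussian target noise (default 0.06).
#' @return List of per-chain lists: `chain`, `sequence`, `alignment`,
#'   `target`, `buried` (logical).
#' @export
make_conservation_set <- function(seed, n_chains = 24, len = 60,
                                  n_homologs = 40, base_effect = 0.05,
                                  burial_effect = 0.35, noise_sd = 0.06) {
  base_shift <- withr::with_seed(seed, stats::rnorm(4, 0, base_effect))
  names(base_shift) <- BASES
  purrr::map(seq_len(n_chains), function(i) {
    sub_seed <- seed + i * 101
    withr::with_seed(sub_seed, {
      s <- random_rna(len)
      buried <- stats::runif(len) < 0.4
      ch <- strsplit(s, "")[[1]]
      target <- pmin(1, pmax(0,
        0.55 - burial_effect * buried + base_shift[ch] +
          stats::rnorm(len, 0, noise_sd)))
    })
    aln <- make_synthetic_alignment(s, seed = sub_seed + 1,
                                    n_homologs = n_homologs,
                                    mutation_rate = 0.45, gap_rate = 0,
                                    conserved = buried)
    list(chain = sprintf("chain%03d", i), sequence = s, alignment = aln,
         target = unname(target), buried = buried)
  })
}

#' Synthetic SNV table with a planted MAF-ASA link
#'
#' Minor allele frequencies follow `maf = link(predicted) * lognormal noise`
#' clamped to (0, 0.5]; region classes and mutation types are assigned at
#' random. With `noise_sd = 0` and an increasing link, the binned
#' association is exactly monotone.
#'
#' @param seed Integer seed.
#' @param n Number of SNVs (default 200).
#' @param link Increasing function predicted -> MAF scale; the default is
#'   affine on the log10 scale (maf = 10^(-3 + 2.5 p)), so noiseless bin
#'   means are exactly collinear.
#' @param noise_sd SD of the multiplicative lognormal noise on the log scale
#'   (default 0).
#' @return Tibble `id`, `region`, `mutation_type`, `predicted`, `maf`.
#' @export
make_snv_table <- function(seed, n = 200,
                           link = function(p) 10^(-3 + 2.5 * p),
                           noise_sd = 0) {
  regions <- c("synonymous", "nonsynonymous", "three_utr", "five_utr", "ncRNA")
  withr::with_seed(seed, {
    predicted <- stats::runif(n)
    noise <- if (noise_sd > 0) exp(stats::rnorm(n, 0, noise_sd)) else 1
    maf <- pmin(0.5, pmax(1e-6, link(predicted) * noise))
    tibble::tibble(
      id = sprintf("snv%05d", seq_len(n)),
      region = sample(regions, n, replace = TRUE),
      mutation_type = sample(c("transition", "transversion"), n,
                             replace = TRUE, prob = c(0.6, 0.4)),
      predicted = predicted,
      maf = maf
    )
  })
}

#' Synthetic DMS read tracks with a planted in-vivo signal
#'
#' All conditions share a positional bias (sequence context, library
#' effects); the in-vivo condition additionally scales with a planted
#' per-base exposure, while the in-vitro condition does not. Normalizing by
#' the denatured control removes the shared bias, so the recovered in-vivo
#' reactivity correlates with exposure and the in-vitro one does not.
#'
#' @param seed Integer seed.
#' @param length Track length in bases (default 5000, the scale of an mRNA
#'   passing the reacted-base filter).
#' @param depth Mean read depth scale (default 200).
#' @param exposure_weight Strength of the exposure term in vivo (default 1).
#' @return List: `track` (tibble `mrna_id`, `position`, `denature`,
#'   `invitro`, `vivo`), `exposure` (per-base truth).
#' @export
make_dms_tracks <- function(seed, length = 5000, depth = 200,
                            exposure_weight = 1) {
  withr::with_seed(seed, {
    bias <- exp(stats::rnorm(length, 0, 0.5))
    exposure <- stats::runif(length)
    lam_den <- depth * bias
    lam_vitro <- depth * bias * exp(stats::rnorm(length, 0, 0.2))
    lam_vivo <- depth * bias * (0.25 + exposure_weight * exposure)
    track <- tibble::tibble(
      mrna_id = "mrna1",
      position = seq_len(length) - 1L,
      denature = stats::rpois(length, lam_den),
      invitro = stats::rpois(length, lam_vitro),
      vivo = stats::rpois(length, lam_vivo)
    )
  })
  list(track = track, exposure = exposure)
}

#' Synthetic transcripts with a planted intron/exon ASA step
#'
#' Each transcript has 5'UTR, alternating CDS/intron segments, and 3'UTR,
#' with per-base ASA at `exon_asa` in exonic regions and `intron_asa` in
#' introns plus Gaussian noise — a step function the boundary profile should
#' recover.
#'
#' @param seed Integer seed.
#' @param n_transcripts Number of transcripts (default 8).
#' @param region_len Bases per region segment (default 120).
#' @param n_introns Introns per transcript (default 2).
#' @param exon_asa,intron_asa Planted levels (defaults 0.3, 0.8).
#' @param noise_sd Per-base noise (default 0).
#' @return List of transcripts in the shape [boundary_profile()] consumes.
#' @export
make_transcript_set <- function(seed, n_transcripts = 8, region_len = 120,
                                n_introns = 2, exon_asa = 0.3,
                                intron_asa = 0.8, noise_sd = 0) {
  purrr::map(seq_len(n_transcripts), function(i) {
    labs <- c("five_utr",
              head(rep(c("cds", "intron"), n_introns + 1), 2 * n_introns + 1),
              "three_utr")
    starts <- (seq_along(labs) - 1L) * region_len
    regions <- tibble::tibble(region = labs, start = starts,
                              end = starts + region_len)
    level <- ifelse(labs == "intron", intron_asa, exon_asa)
    asa <- rep(level, each = region_len)
    if (noise_sd > 0) {
      asa <- withr::with_seed(seed + i, asa + stats::rnorm(length(asa), 0, noise_sd))
    }
    list(asa = asa, regions = regions)
  })
}
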