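test_that("DMS normalization follows the max -> fragment -> drop -> ratio order", {
  # identical compare and denature tracks: every surviving ratio is 1
  set.seed(7)
  counts <- stats::rpois(200, 20)
  tr_same <- tibble::tibble(position = 0:199, denature = counts, vivo = counts)
  same <- normalize_dms(tr_same, "vivo")
  expect_equal(same$reactivity, rep(1, nrow(same)))

  # hand-walk: 100-base mRNA whose max-normalized fragment means are
  # denature (0.5, 0) and vivo (0.4, 0.2) -> one surviving fragment, 0.8
  den <- c(rep(c(1, 0), 25), rep(0, 50))                   # max 1, means .5, 0
  viv <- c(rep(1, 20), rep(0, 30), rep(1, 10), rep(0, 40)) # max 1, means .4, .2
  walk <- normalize_dms(tibble::tibble(position = 0:99, denature = den,
                                       vivo = viv), "vivo")
  expect_equal(nrow(walk), 1)
  expect_equal(walk$fragment_index, 0L)
  expect_equal(walk$reactivity, 0.8)

  # 149-base track: two fragments considered, trailing 49 bases dropped
  tr149 <- tibble::tibble(position = 0:148, denature = rep(1, 149),
                          vivo = rep(1, 149))
  expect_equal(nrow(normalize_dms(tr149, "vivo")), 2)

  expect_error(normalize_dms(tibble::tibble(denature = 0, vivo = 1), "vivo"),
               "zero maximum")
})

test_that("DMS normalization is invariant to rescaling one condition's counts", {
  dm <- make_dms_tracks(40, length = 500)
  a <- normalize_dms(dm$track, "vivo")
  scaled <- dm$track
  scaled$vivo <- scaled$vivo * 17
  b <- normalize_dms(scaled, "vivo")
  expect_equal(a, b)
})

test_that("reacted-base filter keeps only sufficiently covered mRNAs", {
  tracks <- dplyr::bind_rows(
    tibble::tibble(mrna_id = "deep", position = 0:99, vivo = rep(1, 100)),
    tibble::tibble(mrna_id = "shallow", position = 0:99,
                   vivo = c(rep(1, 10), rep(0, 90)))
  )
  kept <- filter_dms_tracks(tracks, "vivo", min_reacted = 50)
  expect_equal(unique(kept$mrna_id), "deep")
})

test_that("MAF binning sorts stably, sizes bins, and recovers a planted link exactly", {
  # n = 200 into 100 bins -> every bin holds exactly 2 records
  snvs <- make_snv_table(31, n = 200)
  ba <- bin_association(snvs, n_bins = 100)
  expect_equal(nrow(ba$bins), 100)
  expect_equal(unique(ba$bins$n), 2)
  expect_equal(sum(ba$bins$n), 200)
  # noiseless log-affine link -> bin means exactly collinear
  expect_equal(ba$r, 1.0)
  # bin means are sorted with the records
  expect_true(!is.unsorted(ba$bins$mean_pred))

  # remainder rule: 205 records -> first 5 bins of 3, rest of 2
  ba2 <- bin_association(make_snv_table(32, n = 205), n_bins = 100)
  expect_equal(ba2$bins$n, c(rep(3, 5), rep(2, 95)))

  # shuffling predicted against MAF destroys the association: permutation null
  null_rs <- vapply(1:200, function(i) {
    sh <- snvs
    sh$predicted <- withr::with_seed(1000 + i, sample(sh$predicted))
    bin_association(sh, n_bins = 100)$r
  }, numeric(1))
  expect_lt(stats::quantile(abs(null_rs), 0.95), 0.5)
  sh1 <- snvs
  sh1$predicted <- withr::with_seed(77, sample(sh1$predicted))
  expect_lt(abs(bin_association(sh1, n_bins = 100)$r),
            stats::quantile(abs(null_rs), 0.95) + 0.2)

  # preconditions
  expect_error(bin_association(make_snv_table(33, n = 50), n_bins = 100),
               "at least 100")
  bad <- snvs; bad$maf[1] <- 0
  expect_message(bin_association(dplyr::bind_rows(bad, bad), n_bins = 100),
                 "rejected")
})

test_that("pre-sorted input yields identical bins (sort stability)", {
  snvs <- make_snv_table(34, n = 300, noise_sd = 0.5)
  ba <- bin_association(snvs, n_bins = 100)
  ba_sorted <- bin_association(snvs[order(snvs$predicted), ], n_bins = 100)
  expect_equal(ba$bins, ba_sorted$bins)
})

test_that("stratified association recovers opposite planted signs per stratum", {
  up <- make_snv_table(35, n = 150)
  down <- make_snv_table(36, n = 150, link = function(p) 10^(-1 - 2.5 * p))
  up$region <- "synonymous"; down$region <- "ncRNA"
  both <- dplyr::bind_rows(up, down)
  st <- stratified_bin_association(both, "region", n_bins = 100)
  expect_equal(st$r[st$stratum == "synonymous"], 1.0)
  expect_equal(st$r[st$stratum == "ncRNA"], -1.0)
  expect_equal(sum(st$n), 300)

  # single stratum == plain bin_association
  one <- stratified_bin_association(up, "region", n_bins = 100)
  expect_equal(one$r, bin_association(up, n_bins = 100)$r)

  # undersized stratum skipped with warning, not merged
  small <- make_snv_table(37, n = 50); small$region <- "five_utr"
  expect_warning(st2 <- stratified_bin_association(
    dplyr::bind_rows(up, small), "region", n_bins = 100), "skipped")
  expect_true(is.na(st2$r[st2$stratum == "five_utr"]))
})

test_that("boundary profiles average per offset and recover a planted step", {
  # constant ASA -> constant profile
  const <- make_transcript_set(50, n_transcripts = 1, exon_asa = 0.5,
                               intron_asa = 0.5)
  bp <- boundary_profile(const)
  expect_equal(unique(bp$profile$mean_asa), 0.5)
  expect_setequal(unique(bp$profile$boundary),
                  c("five_utr|cds", "cds|intron", "intron|cds", "cds|three_utr"))
  expect_equal(sort(unique(bp$profile$offset)), -50:49)

  # two flat transcripts at 0.2 and 0.8 -> mean 0.5 everywhere
  two <- c(make_transcript_set(51, 1, exon_asa = 0.2, intron_asa = 0.2),
           make_transcript_set(52, 1, exon_asa = 0.8, intron_asa = 0.8))
  expect_equal(unique(boundary_profile(two)$profile$mean_asa), 0.5)

  # planted step: introns 0.8, exons 0.3, step exactly at the boundary
  step <- boundary_profile(make_transcript_set(53, n_transcripts = 4))
  ci <- step$profile[step$profile$boundary == "cds|intron", ]
  expect_equal(ci$mean_asa[ci$offset < 0], rep(0.3, 50))
  expect_equal(ci$mean_asa[ci$offset >= 0], rep(0.8, 50))
  ic <- step$profile[step$profile$boundary == "intron|cds", ]
  expect_equal(ic$mean_asa[ic$offset < 0], rep(0.8, 50))

  # means bounded by contributing values
  noisy <- boundary_profile(make_transcript_set(54, n_transcripts = 6,
                                                noise_sd = 0.05))
  expect_true(all(noisy$profile$mean_asa > 0 & noisy$profile$mean_asa < 1))

  # transcripts failing the region-length filter are excluded and counted
  short <- make_transcript_set(55, n_transcripts = 1, region_len = 60)
  mix <- c(make_transcript_set(56, n_transcripts = 2), short)
  bp_mix <- boundary_profile(mix, min_region = 100)
  expect_equal(bp_mix$n_used, 2)
  expect_equal(bp_mix$n_excluded, 1)
})
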