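cfg <- methodConfig()

test_that("fixed thresholding keeps exactly the voxels at or above SUV", {
  a <- array(1, c(3, 3, 3)); a[2, 2, 2] <- 10
  img <- SUVImage(a)
  expect_equal(sum(maskArray(segmentFixed(img, 4))), 1L)
  expect_true(maskArray(segmentFixed(img, 4))[2, 2, 2])
  expect_equal(sum(maskArray(segmentFixed(SUVImage(array(1, c(3, 3, 3))),
                                          4))), 0L)
  ph <- separablePhantom()
  m <- segmentFixed(ph$image, 4)
  truthAll <- lesionLabels(ph$truth) > 0 | lesionLabels(ph$physio) > 0
  expect_equal(maskArray(m), truthAll)
})

test_that("fixed masks are monotone non-increasing in the threshold", {
  set.seed(21)
  img <- SUVImage(array(runif(12^3, 0, 12), c(12, 12, 12)))
  m1 <- maskArray(segmentFixed(img, 2.5))
  m2 <- maskArray(segmentFixed(img, 4))
  m3 <- maskArray(segmentFixed(img, 7))
  expect_true(all(m2 <= m1) && all(m3 <= m2))
})

test_that("SUVpeak matches uniform expectations and never exceeds SUVmax", {
  img <- SUVImage(array(5, c(9, 9, 9)), spacing = c(3.2, 3.2, 2))
  reg <- array(FALSE, c(9, 9, 9)); reg[5, 5, 5] <- TRUE
  expect_equal(computeSUVpeak(img, BinaryMask(reg, img)), 5)

  # large uniform hot sphere: the 1 mL sphere fits inside -> mean 8
  ph <- generatePhantom(
    lesions = data.frame(x = 0, y = 0, z = 0, diameter = 40, suv = 8),
    shape = c(32, 32, 32), fwhm = 0, noiseSd = 0)
  ctr <- array(FALSE, dim(suvValues(ph$image)))
  ctr[worldToVoxel(ph$image, c(0, 0, 0))[1],
      worldToVoxel(ph$image, c(0, 0, 0))[2],
      worldToVoxel(ph$image, c(0, 0, 0))[3]] <- TRUE
  expect_equal(computeSUVpeak(ph$image, BinaryMask(ctr, ph$image)), 8)

  set.seed(31)
  for (rep in 1:4) {
    vals <- array(runif(15^3, 0, 10), c(15, 15, 15))
    img <- SUVImage(vals, spacing = c(3.2, 3.2, 2))
    reg <- array(runif(15^3) < 0.1, c(15, 15, 15))
    if (!any(reg)) next
    pk <- computeSUVpeak(img, BinaryMask(reg, img))
    expect_equal(pk, suvpeakOracle(vals, c(3.2, 3.2, 2), reg))
    expect_lte(pk, max(vals[reg]) + 1e-12)
  }
})

test_that("candidate detection equals components of the detection mask", {
  ph <- separablePhantom()
  cands <- detectCandidates(ph$image, cfg)
  det <- segmentFixed(ph$image, cfg@detectionThreshold)
  expect_equal(lesionLabels(cands) > 0, maskArray(det))
  expect_equal(nrow(lesionTable(cands)), 5L)  # 4 lesions + 1 physio
  expect_equal(nrow(lesionTable(detectCandidates(
    SUVImage(array(1, c(6, 6, 6)))))), 0L)
})

test_that("41MAX thresholds at 41% of the candidate maximum", {
  # lesion with SUVmax 10: effective threshold 4.1 keeps >= 4.1 only
  a <- array(1, c(9, 9, 9))
  a[4:6, 4:6, 4:6] <- 5
  a[5, 5, 5] <- 10
  a[4, 4, 4] <- 4.05   # just below 0.41 * 10
  img <- SUVImage(a, spacing = c(2, 2, 2))
  cand <- BinaryMask(a >= 2.5, img)
  m <- maskArray(segment41Max(img, cand, cfg))
  expect_true(all(a[m] >= 4.1))
  expect_false(m[4, 4, 4])
  expect_true(m[5, 5, 5])

  ph <- separablePhantom()
  cands <- detectCandidates(ph$image, cfg)
  big <- lesionMask(cands, 1L)
  seg <- segment41Max(ph$image, big, cfg)
  expect_equal(maskArray(seg), maskArray(big))
})

test_that("local background equals an explicit shell-voxel average", {
  ph <- generatePhantom(
    lesions = data.frame(x = 0, y = 0, z = 0, diameter = 16, suv = 8),
    shape = c(24, 24, 24), fwhm = 0, noiseSd = 0)
  reg <- lesionMask(ph$truth, 1L)
  expect_equal(estimateLocalBackground(ph$image, reg, cfg), 1)

  # gradient background: compare against direct enumeration of the shell
  d <- c(20, 20, 20)
  grad <- array(rep(seq(1, 3, length.out = d[1]), times = prod(d[2:3])), d)
  img <- SUVImage(grad, spacing = c(2, 2, 2))
  regArr <- array(FALSE, d); regArr[10:11, 10:11, 10:11] <- TRUE
  reg <- BinaryMask(regArr, img)
  b <- estimateLocalBackground(img, reg, cfg)
  # enumerate: Chebyshev distance from the region in (2,5]
  all <- arrayInd(seq_len(prod(d)), d)
  rvox <- arrayInd(which(regArr), d)
  cheb <- apply(all, 1, function(v)
    min(apply(abs(sweep(rvox, 2, v)), 1, max)))
  shell <- cheb > 2 & cheb <= 5
  expect_equal(b, mean(grad[shell]))
  expect_gt(b, 1); expect_lt(b, 3)

  # region filling the whole grid leaves no shell
  full <- BinaryMask(array(TRUE, d), img)
  expect_error(estimateLocalBackground(img, full, cfg), "shell")
})

test_that("A50P applies the contrast-corrected threshold B + f(P - B)", {
  # uniform SUV-10 sphere on background 2: P = 10, B = 2 -> T = 6
  ph <- generatePhantom(
    lesions = data.frame(x = 0, y = 0, z = 0, diameter = 24, suv = 10),
    shape = c(28, 28, 28), background = 2, fwhm = 0, noiseSd = 0)
  cand <- lesionMask(ph$truth, 1L)
  # independent threshold computation
  P <- suvpeakOracle(suvValues(ph$image), gridSpacing(ph$image),
                     maskArray(cand))
  B <- estimateLocalBackground(ph$image, cand, cfg)
  expect_equal(P, 10); expect_equal(B, 2)
  Tthr <- B + 0.5 * (P - B)
  expect_equal(Tthr, 6)
  seg <- segmentA50P(ph$image, cand, cfg)
  expect_equal(maskArray(seg), suvValues(ph$image) >= Tthr)

  # B = 0 limit: pure 50% of peak
  ph0 <- generatePhantom(
    lesions = data.frame(x = 0, y = 0, z = 0, diameter = 24, suv = 8),
    shape = c(28, 28, 28), background = 0, fwhm = 0, noiseSd = 0)
  cand0 <- lesionMask(ph0$truth, 1L)
  seg0 <- segmentA50P(ph0$image, cand0, cfg)
  expect_equal(maskArray(seg0), suvValues(ph0$image) >= 4)
})

test_that("adaptive masks are scale invariant, fixed masks are not", {
  ph <- generatePhantom(
    lesions = data.frame(x = c(-20, 14), y = c(-12, 12), z = c(0, 6),
                         diameter = c(20, 16), suv = c(8, 6)),
    shape = c(32, 32, 24), fwhm = 0, noiseSd = 0)
  img <- ph$image
  cands <- detectCandidates(img, cfg)
  for (cc in c(0.5, 3)) {
    scaled <- SUVImage(suvValues(img) * cc, gridSpacing(img),
                       gridOrigin(img))
    for (id in lesionTable(cands)$id) {
      cm <- lesionMask(cands, id)
      expect_equal(maskArray(segment41Max(scaled, cm, cfg)),
                   maskArray(segment41Max(img, cm, cfg)))
      expect_equal(maskArray(segmentA50P(scaled, cm, cfg)),
                   maskArray(segmentA50P(img, cm, cfg)))
    }
  }
  # fixed thresholds do depend on the absolute scale
  half <- SUVImage(suvValues(img) * 0.5, gridSpacing(img), gridOrigin(img))
  triple <- SUVImage(suvValues(img) * 3, gridSpacing(img), gridOrigin(img))
  expect_false(identical(maskArray(segmentFixed(half, 4)),
                         maskArray(segmentFixed(img, 4))))
  expect_false(identical(maskArray(segmentFixed(triple, 2.5)),
                         maskArray(segmentFixed(img, 2.5))))
})

test_that("majority vote equals per-voxel counting and nests correctly", {
  v <- array(TRUE, c(2, 2, 2))
  mk <- function(on) BinaryMask(array(on, c(2, 2, 2)), spacing = c(1, 1, 1))
  only25and40 <- list(mk(TRUE), mk(TRUE), mk(FALSE), mk(FALSE))
  expect_true(all(maskArray(majorityVote(only25and40, 2))))
  expect_false(any(maskArray(majorityVote(only25and40, 3))))
  allFour <- list(mk(TRUE), mk(TRUE), mk(TRUE), mk(TRUE))
  expect_true(all(maskArray(majorityVote(allFour, 2))))
  expect_true(all(maskArray(majorityVote(allFour, 3))))

  set.seed(61)
  for (rep in 1:10) {
    ms <- lapply(1:4, function(i) randomMask(c(6, 6, 6)))
    counts <- Reduce(`+`, lapply(ms, function(m)
      array(as.integer(maskArray(m)), c(6, 6, 6))))
    mv2 <- maskArray(majorityVote(ms, 2))
    mv3 <- maskArray(majorityVote(ms, 3))
    expect_equal(mv2, counts >= 2)
    expect_equal(mv3, counts >= 3)
    inter <- Reduce(`&`, lapply(ms, maskArray))
    un <- Reduce(`|`, lapply(ms, maskArray))
    expect_true(all(inter <= mv3) && all(mv3 <= mv2) && all(mv2 <= un))
  }
  bad <- list(mk(TRUE), mk(TRUE), mk(TRUE),
              BinaryMask(array(TRUE, c(3, 3, 3)), spacing = c(1, 1, 1)))
  expect_error(majorityVote(bad, 2), "mismatch")
})

test_that("the 3 mL rule removes a 146-voxel blob and keeps 147 voxels", {
  # on the 3.2 x 3.2 x 2 mm grid the boundary is 3 / 0.02048 = 146.48
  d <- c(24, 24, 12)
  m <- array(FALSE, d)
  m[2:8, 2:8, 2:4] <- TRUE          # 7*7*3 = 147 voxels = 3.011 mL
  m2 <- array(FALSE, d)
  m2[14:20, 14:20, 8:10] <- TRUE
  m2[14, 14, 8] <- FALSE            # 146 voxels = 2.990 mL
  img <- SUVImage(array(1, d), spacing = c(3.2, 3.2, 2))
  ls <- connectedComponents(BinaryMask(m | m2, img))
  expect_equal(nrow(lesionTable(ls)), 2L)
  kept <- applyMinVolume(ls, cfg)
  expect_equal(lesionTable(kept)$voxels, 147L)
  expect_true(all(lesionTable(kept)$volume_ml >= 3))
  expect_lte(matv(kept), matv(ls))

  # threshold 0 is the identity; everything below threshold empties
  cfg0 <- methodConfig(minLesionVolume = 0)
  expect_equal(lesionTable(applyMinVolume(ls, cfg0)),
               lesionTable(ls))
  cfgBig <- methodConfig(minLesionVolume = 100)
  expect_equal(nrow(lesionTable(applyMinVolume(ls, cfgBig))), 0L)
  expect_equal(matv(applyMinVolume(ls, cfgBig)), 0)
})

test_that("full method runs recover separable spheres and drop small ones", {
  ph <- generatePhantom(
    lesions = data.frame(x = 0, y = 0, z = 0, diameter = 21.2, suv = 8),
    shape = c(24, 24, 24), fwhm = 0, noiseSd = 0)  # ~5 mL
  r <- runMethod(ph$image, "SUV40")
  expect_equal(nrow(lesionTable(r)), 1L)
  expect_equal(lesionLabels(r) > 0, lesionLabels(ph$truth) > 0)

  small <- generatePhantom(
    lesions = data.frame(x = 0, y = 0, z = 0, diameter = 12.4, suv = 8),
    shape = c(24, 24, 24), fwhm = 0, noiseSd = 0)  # ~1 mL < 3 mL
  r2 <- runMethod(small$image, "SUV40")
  expect_equal(nrow(lesionTable(r2)), 0L)
  expect_equal(matv(r2), 0)
})

test_that("MV3 equals chaining the individual stages by hand", {
  ph <- separablePhantom()
  img <- ph$image
  r <- runMethod(img, "MV3", cfg)
  # stage-by-stage: four whole-image base masks, vote, components, 3 mL
  cands <- detectCandidates(img, cfg)
  adaptiveUnion <- function(fun) {
    u <- array(FALSE, dim(suvValues(img)))
    for (id in lesionTable(cands)$id)
      u <- u | maskArray(fun(lesionMask(cands, id)))
    BinaryMask(u, img)
  }
  det <- segmentFixed(img, cfg@detectionThreshold)
  base <- list(
    segmentFixed(img, cfg@fixedThresholdSuv25),
    segmentFixed(img, cfg@fixedThresholdSuv40),
    adaptiveUnion(function(cm) segment41Max(img, cm, cfg)),
    adaptiveUnion(function(cm) segmentA50P(img, cm, cfg, exclude = det)))
  byHand <- applyMinVolume(connectedComponents(majorityVote(base, 3)), cfg)
  expect_equal(lesionLabels(r), lesionLabels(byHand))
  expect_equal(lesionTable(r)$voxels, lesionTable(byHand)$voxels)
})
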