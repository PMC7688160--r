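test_that("fuzzy c-means separates a bimodal image at the mode boundary", {
  set.seed(1)
  img <- matrix(0, 40, 40)
  bright <- sample(length(img), 400)
  img[] <- rnorm(length(img), 100, 5)
  img[bright] <- rnorm(400, 10000, 50)
  fg <- fcm_foreground(img)
  expect_setequal(which(fg), bright)
  # same partition as a midpoint threshold between well-separated modes
  expect_identical(fg[, ], (img > 5000)[, ])
})

test_that("constant images cannot be clustered", {
  expect_error(fcm_foreground(matrix(7, 10, 10)), "degenerate")
})

test_that("foreground of a single bright disc matches its area", {
  sim <- simulate_fluorescence(n_nuclei = 1, n_touching_pairs = 0,
                               marker_coverage = 0.6, dim = c(96, 96),
                               seed = 5)
  fg <- fcm_foreground(sim$dapi, sim$roi)
  expect_equal(sum(fg), sim$truth$area, tolerance = 0.1)
  expect_equal(nrow(sim$truth), 1)
  expect_equal(sim$truth$coverage, 0.6, tolerance = 0.02)
})

test_that("watershed splits touching discs and leaves singles intact", {
  two <- disc_mask(c(60, 60), rbind(c(25, 30), c(41, 30)), c(10, 10))
  expect_equal(max(watershed_split(two)), 2)
  one <- disc_mask(c(40, 40), rbind(c(20, 20)), 9)
  expect_equal(max(watershed_split(one)), 1)
  empty <- matrix(FALSE, 30, 30)
  expect_equal(max(watershed_split(empty)), 0)
  # min-area filter removes debris
  small <- disc_mask(c(30, 30), rbind(c(15, 15)), 2)
  expect_equal(max(watershed_split(small, min_area = 25)), 0)
})

test_that("concave splitting cuts a two-lobed clump into its lobes", {
  # a figure-eight the watershed failed on: present it as one label
  clump <- disc_mask(c(70, 50), rbind(c(22, 25), c(40, 25)), c(11, 11))
  lab <- matrix(0L, 70, 50); lab[clump] <- 1L
  out <- concave_split(lab)
  expect_equal(max(out), 2)
  areas <- tabulate(out[out > 0])
  expect_true(all(areas >= 25))
  expect_equal(sum(areas), sum(clump))  # no pixels lost
})

test_that("convex objects and guarded cuts are left unchanged", {
  one <- disc_mask(c(40, 40), rbind(c(20, 20)), 10)
  lab <- matrix(0L, 40, 40); lab[one] <- 1L
  expect_identical(concave_split(lab), lab)
  # two lobes, one below min-area: the guard forbids the cut
  clump <- disc_mask(c(60, 40), rbind(c(20, 20), c(31, 20)), c(10, 4))
  lab2 <- matrix(0L, 60, 40); lab2[clump] <- 1L
  out2 <- concave_split(lab2, min_area = 60)
  expect_equal(max(out2), 1)
  expect_equal(sum(out2 > 0), sum(clump))
})

test_that("concave splitting is idempotent", {
  set.seed(11)
  for (rep in 1:5) {
    r <- runif(1, 8, 12)
    d <- runif(1, 1.4, 1.7) * r
    clump <- disc_mask(c(80, 60), rbind(c(30, 30), c(30 + d, 30)), c(r, r))
    lab <- matrix(0L, 80, 60); lab[clump] <- 1L
    once <- concave_split(lab)
    twice <- concave_split(once)
    expect_identical(twice, once)
  }
})

test_that("the marker threshold is the ROI median with strict positivity", {
  img <- matrix(1:100, 10, 10)
  roi <- matrix(TRUE, 10, 10)
  thr <- marker_threshold(img, roi)
  expect_equal(thr, 50.5)
  expect_equal(sum(img > thr), 50)
  expect_error(marker_threshold(img, matrix(FALSE, 10, 10)), "empty ROI")
  # constant image: nothing exceeds its own median
  expect_equal(asma_area_fraction(matrix(3, 8, 8), matrix(TRUE, 8, 8)), 0)
})

test_that("positive masks are invariant under strictly increasing transforms", {
  set.seed(3)
  img <- matrix(runif(64 * 64, 0, 1000), 64, 64)
  roi <- matrix(TRUE, 64, 64)
  f <- function(x) x^3 / 1e4 + 17          # strictly increasing
  thr1 <- marker_threshold(img, roi)
  thr2 <- marker_threshold(f(img), roi)
  expect_identical(img > thr1, f(img) > thr2)
  expect_identical(asma_area_fraction(img, roi),
                   asma_area_fraction(f(img), roi))
  # continuous noise-only image sits at one half by the median property
  expect_equal(asma_area_fraction(img, roi), 0.5, tolerance = 0.01)
})

test_that("nuclear positivity applies the strict 50% coverage rule", {
  lab <- matrix(0L, 20, 10)
  lab[1:10, 1:10] <- 1L    # nucleus 1: 100 px
  lab[11:20, 1:10] <- 2L   # nucleus 2: 100 px
  marker <- matrix(0, 20, 10)
  marker[1:10, 1:6] <- 100   # coverage 0.6
  marker[11:20, 1:5] <- 100  # coverage exactly 0.5
  mq <- runx2_positivity(lab, marker, threshold = 50)
  expect_equal(mq$records$coverage, c(0.6, 0.5))
  expect_identical(mq$records$positive, c(TRUE, FALSE))
  expect_equal(mq$positive_fraction, 0.5)
  expect_error(runx2_positivity(matrix(0L, 5, 5), matrix(0, 5, 5), 1),
               "no nuclei")
})

test_that("positivity fraction is the mean of per-nucleus calls", {
  lab <- matrix(0L, 40, 10)
  for (k in 1:4) lab[(10 * k - 9):(10 * k), ] <- k
  marker <- matrix(0, 40, 10)
  cov <- c(0.6, 0.6, 0.4, 0.4)
  for (k in 1:4) marker[(10 * k - 9):(10 * k), seq_len(10 * cov[k])] <- 9
  mq <- runx2_positivity(lab, marker, threshold = 1)
  expect_equal(mq$positive_fraction, 0.5)
  expect_equal(mq$n_nuclei, 4)
})

test_that("label masks partition the foreground disjointly", {
  sim <- simulate_fluorescence(n_nuclei = 40, n_touching_pairs = 4,
                               dim = c(256, 256), seed = 13)
  lab <- segment_nuclei(sim$dapi, sim$roi)
  expect_gt(max(lab), 0)
  # every labeled pixel carries exactly one label by construction;
  # labels are sequential with no gaps
  expect_setequal(sort(unique(lab[lab > 0])), seq_len(max(lab)))
  areas <- tabulate(lab[lab > 0])
  expect_true(all(areas >= 25))
})

test_that("nucleus counts are recovered on a synthetic field", {
  sim <- simulate_fluorescence(n_nuclei = 60, n_touching_pairs = 6,
                               dim = c(400, 400), seed = 17)
  lab <- segment_nuclei(sim$dapi, sim$roi)
  expect_equal(max(lab), 60, tolerance = 0.05)
})
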