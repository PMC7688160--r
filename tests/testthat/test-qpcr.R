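test_that("delta-Ct subtracts the geometric mean of the housekeeping pair", {
  tab <- data.frame(sample = "s1", target = c("Acta2", "Gapdh", "Actb"),
                    cq = c(25, 20, 22))
  out <- delta_ct(tab)
  expect_equal(out$delta_ct, 25 - sqrt(440), tolerance = 1e-12)
  expect_equal(out$hk_ref, sqrt(20 * 22), tolerance = 1e-12)
  # equal housekeeping Cqs reduce to simple subtraction
  tab2 <- data.frame(sample = "s1", target = c("Acta2", "Gapdh", "Actb"),
                     cq = c(25, 20, 20))
  expect_equal(delta_ct(tab2)$delta_ct, 5)
})

test_that("missing housekeeping rows fail naming the sample", {
  tab <- data.frame(sample = c("s1", "s1", "s2", "s2", "s2"),
                    target = c("Acta2", "Gapdh", "Acta2", "Gapdh", "Actb"),
                    cq = c(25, 20, 24, 20, 22))
  expect_error(delta_ct(tab), "s1")
})

test_that("technical replicates are averaged and undetermined wells dropped", {
  tab <- data.frame(sample = "s1",
                    target = c("Acta2", "Acta2", "Gapdh", "Actb", "Acta2"),
                    cq = c(24, 26, 20, 20, NA))
  expect_warning(out <- delta_ct(tab), "undetermined")
  expect_equal(out$cq, 25)
  expect_equal(out$delta_ct, 5)
  expect_error(suppressWarnings(
    delta_ct(data.frame(sample = "s1", target = c("A", "Gapdh", "Actb"),
                        cq = c(-1, 20, 20)))), "positive")
})

test_that("simulated Cq tables honour their ground truth", {
  gdef <- list(list(name = "WT", n = 4,
                    mean_cq = c(Gapdh = 20, Actb = 22, Acta2 = 25), sd = 0),
               list(name = "KO", n = 4,
                    mean_cq = c(Gapdh = 20, Actb = 22, Acta2 = 25), sd = 0))
  tab <- simulate_ct_table(gdef, seed = 1)
  out <- delta_ct(tab)
  expect_true(all(abs(out$delta_ct - (25 - sqrt(440))) < 1e-9))
  # identical group means: zero expected group difference
  gm <- tapply(out$delta_ct, out$group, mean)
  expect_equal(unname(diff(gm)), 0)
  expect_identical(simulate_ct_table(gdef, seed = 3),
                   simulate_ct_table(gdef, seed = 3))
  expect_error(simulate_ct_table(list(list(name = "WT", n = 4,
    mean_cq = c(Gapdh = 20, Acta2 = 25), sd = 0))), "housekeeping")
})

test_that("planted group differences in target Cq pass straight into delta-Ct", {
  gdef <- list(list(name = "WT", n = 40,
                    mean_cq = c(Gapdh = 20, Actb = 22, Acta2 = 25), sd = 0.3),
               list(name = "KO", n = 40,
                    mean_cq = c(Gapdh = 20, Actb = 22, Acta2 = 26.5), sd = 0.3))
  out <- delta_ct(simulate_ct_table(gdef, seed = 7))
  gm <- tapply(out$delta_ct, out$group, mean)
  expect_equal(gm[["KO"]] - gm[["WT"]], 1.5, tolerance = 3 * 0.3 / sqrt(20))
})

test_that("a constant shift of one target's Cq shifts its delta-Ct exactly", {
  tab <- data.frame(sample = rep(c("s1", "s2"), each = 3),
                    target = rep(c("Acta2", "Gapdh", "Actb"), 2),
                    cq = c(25, 20, 22, 27, 21, 23))
  base <- delta_ct(tab)
  tab2 <- tab
  tab2$cq[tab2$target == "Acta2"] <- tab2$cq[tab2$target == "Acta2"] + 1.75
  expect_equal(delta_ct(tab2)$delta_ct, base$delta_ct + 1.75)
})

test_that("fold changes follow 2^-ddCt with a unit reference mean", {
  dct <- data.frame(sample = paste0("s", 1:6),
                    group = rep(c("WT", "KO"), each = 3),
                    target = "Acta2", cq = 25,
                    hk_ref = 21, delta_ct = c(4, 5, 6, 3, 4, 8))
  out <- relative_expression(dct, "WT")
  expect_equal(out$ddct[1:3], c(-1, 0, 1))
  expect_equal(out$fold[1:3], c(2, 1, 0.5))
  expect_equal(out$fold[out$sample == "s6"], 2^(-3))
  # the reference group's mean ddCt is zero, hence mean fold exactly 1
  expect_equal(2^(-mean(out$ddct[out$group == "WT"])), 1)
  expect_error(relative_expression(dct, "nope"), "empty")
})

test_that("stats_input hands untransformed delta-Ct values per group", {
  dct <- data.frame(sample = paste0("s", 1:6),
                    group = rep(c("WT", "KO"), each = 3),
                    target = "Acta2", cq = 25, hk_ref = 21,
                    delta_ct = c(4, 5, 6, 3, 4, 8))
  g <- stats_input(dct)
  expect_named(g, c("KO", "WT"))
  expect_equal(g$WT, c(4, 5, 6))
  one <- dct[dct$group == "WT", ]
  expect_error(stats_input(one), "two groups")
  dct2 <- rbind(dct, transform(dct, target = "Ccn2"))
  expect_error(stats_input(dct2), "multiple targets")
  expect_length(stats_input(dct2, "Ccn2"), 2)
})
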