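# Generators: determinism, calibration against their configured models,
# and ledger conservation.

test_that("tissue generation is a pure function of config and seed", {
  cfg <- tiny_config()
  t1 <- gen_tissue(cfg, seed = 5)
  t2 <- gen_tissue(cfg, seed = 5)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- gen_tissue(cfg, seed = 6)
  expect_false(identical(t1$x, t3$x))
})

test_that("single-population config labels every lineage cell accordingly", {
  cfg <- sim_config(field = c(256L, 256L), n_cells = 25L,
                    regions = data.frame(region = "WM", xmin = 0, xmax = 256),
                    lineage_fraction = c(WM = 1),
                    proportions = list(WM = c("MOL2" = 1)))
  tissue <- gen_tissue(cfg, seed = 1)
  expect_true(all(tissue$population == "MOL2"))
})

test_that("nuclei respect the packing margin and field bounds", {
  cfg <- tiny_config()
  tissue <- gen_tissue(cfg, seed = 2)
  d <- as.matrix(dist(cbind(tissue$x, tissue$y)))
  diag(d) <- Inf
  expect_true(min(d) > 2 * max(cfg$radius_range) + cfg$margin)
  expect_true(all(tissue$x - tissue$radius >= 0))
  expect_true(all(tissue$x + tissue$radius <= cfg$field[1] - 1))
})

test_that("infeasible packing fails with an explicit error", {
  cfg <- sim_config(field = c(64L, 64L), n_cells = 200L)
  expect_error(gen_tissue(cfg, seed = 1, max_tries = 50), "infeasible packing")
})

test_that("sampled population proportions match the configured mix", {
  # one region, lineage-only, MOL2 at 0.30: binomial oracle at 3 SE
  n <- 500L
  cfg <- sim_config(field = c(1600L, 1600L), n_cells = n,
                    regions = data.frame(region = "WM", xmin = 0, xmax = 1600),
                    lineage_fraction = c(WM = 1),
                    proportions = list(WM = c("MOL2" = 0.3, "MOL5/6" = 0.7)))
  tissue <- gen_tissue(cfg, seed = 9)
  p_hat <- mean(tissue$population == "MOL2")
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(p_hat - 0.3), 3 * se)
})

test_that("rendered nuclei produce exact disks and labels", {
  cfg <- tiny_config()
  tissue <- gen_tissue(cfg, seed = 4)
  imgs <- render_nuclei_image(tissue)
  expect_equal(length(setdiff(unique(as.vector(imgs$labels)), 0L)),
               nrow(tissue))
  centers <- cbind(round(tissue$y) + 1, round(tissue$x) + 1)
  expect_true(all(imgs$image[centers] > 0.05))
  expect_equal(imgs$labels[centers], tissue$cell)

  empty <- tissue[0, ]
  attr(empty, "config") <- cfg
  blank <- render_nuclei_image(empty)
  expect_true(all(blank$labels == 0L))
  expect_equal(length(unique(as.vector(blank$image))), 1L)
})

test_that("ISS spot counts are calibrated and fully ledgered", {
  # >= 100 MOL5/6 cells; Ptgds mean 12 within 3 Poisson SEs
  cfg <- sim_config(field = c(1500L, 1500L), n_cells = 120L,
                    regions = data.frame(region = "GM", xmin = 0, xmax = 1500),
                    lineage_fraction = c(GM = 1),
                    proportions = list(GM = c("MOL5/6" = 1)),
                    noise = 0, crosstalk = 0)
  tissue <- gen_tissue(cfg, seed = 11)
  sim <- gen_iss_spots(tissue, default_barcode_book(), cfg, seed = 12)
  led <- sim$ledger
  expect_equal(nrow(sim$spots), nrow(led))  # ledger conservation
  ptgds <- led[led$gene == "Ptgds", ]
  per_cell <- table(factor(ptgds$cell, levels = tissue$cell))
  mu <- 12
  se <- sqrt(mu / nrow(tissue))
  expect_lt(abs(mean(per_cell) - mu), 3 * se)
  # spots fall inside their generating cell disk
  idx <- match(led$cell, tissue$cell)
  d <- sqrt((sim$spots$x - tissue$x[idx])^2 + (sim$spots$y - tissue$y[idx])^2)
  expect_true(all(d <= tissue$radius[idx] + 1e-9))
})

test_that("background spots are flagged and only appear when requested", {
  cfg <- tiny_config()
  sim <- gen_iss_spots(gen_tissue(cfg, seed = 1), default_barcode_book(),
                       cfg, seed = 2)
  expect_true(all(!is.na(sim$ledger$cell)))  # rate 0: every spot has a cell

  cfg_bg <- tiny_config(background_rate = 30)
  sim_bg <- gen_iss_spots(gen_tissue(cfg_bg, seed = 1),
                          default_barcode_book(), cfg_bg, seed = 2)
  expect_gt(sum(is.na(sim_bg$ledger$cell)), 0L)
})

test_that("puncta counts hit their configured model", {
  cfg <- sim_config(field = c(1500L, 1500L), n_cells = 150L,
                    regions = data.frame(region = "WM", xmin = 0, xmax = 1500),
                    lineage_fraction = c(WM = 1),
                    proportions = list(WM = c("MOL5/6" = 1)))
  tissue <- gen_tissue(cfg, seed = 21)
  # Poisson limit: sample variance tracks the mean
  pc <- gen_puncta_counts(tissue, dispersion = Inf, seed = 22)
  x <- pc$cells$Ptgds
  mu <- 36  # 3x the Ptgds cutoff
  expect_lt(abs(mean(x) - mu), 3 * sqrt(mu / length(x)))
  # var/mean ratio ~ 1 for Poisson; chi-square spread at n=150 stays < 1.35
  expect_lt(abs(var(x) / mean(x) - 1), 0.35)

  # population with mean 0 gives all-zero counts
  means <- default_puncta_means()
  means["MOL5/6", "Klk6"] <- 0
  pc0 <- gen_puncta_counts(tissue, means = means, seed = 23)
  expect_true(all(pc0$cells$Klk6 == 0))

  # determinism
  expect_identical(gen_puncta_counts(tissue, seed = 24),
                   gen_puncta_counts(tissue, seed = 24))
})

test_that("expression matrix plants what its ledger says", {
  cfg <- expr_sim_config(n_cells = 400L, n_genes = 80L, n_spatial = 10L,
                         spatial_deterministic = TRUE, seed = 31)
  sim <- gen_expression_matrix(cfg)
  tg <- sim$truth$genes
  expect_equal(sum(tg$de), cfg$n_de)
  expect_true(all(tg$true_lfc[!tg$de] == 0))
  expect_equal(sum(tg$spatial), cfg$n_spatial)

  # deterministic spatial genes are an exact function of the embedding
  # (up to the planted library-size outliers and integer rounding)
  g <- tg$gene[tg$spatial][1]
  strength <- tg$spatial_strength[tg$gene == g]
  s1 <- as.numeric(scale(sim$embedding[, 1]))
  plain <- sim$truth$cells$size_factor == 1
  expect_gt(cor(sim$counts[plain, g], 1 + 0.9 * tanh(strength * s1[plain])),
            0.99)
  rerun <- gen_expression_matrix(cfg)
  expect_identical(rerun$counts[, g], sim$counts[, g])

  # a zero-LFC configuration is ledgered as non-DE
  cfg0 <- expr_sim_config(n_cells = 100L, n_genes = 50L, n_de = 5L,
                          de_lfc = 0, seed = 32)
  sim0 <- gen_expression_matrix(cfg0)
  expect_true(all(!sim0$truth$genes$de))
})

test_that("MTX output is byte-identical across reruns and round-trips", {
  cfg <- expr_sim_config(n_cells = 120L, n_genes = 40L, n_de = 5L,
                         n_marker = 2L, n_spatial = 5L, seed = 41)
  d1 <- file.path(tempdir(), "mtx1"); d2 <- file.path(tempdir(), "mtx2")
  sim1 <- gen_expression_matrix(cfg)
  sim2 <- gen_expression_matrix(cfg)
  write_counts_mtx(sim1$counts, d1)
  write_counts_mtx(sim2$counts, d2)
  expect_identical(readBin(file.path(d1, "matrix.mtx"), "raw", 1e6),
                   readBin(file.path(d2, "matrix.mtx"), "raw", 1e6))
  back <- read_counts_mtx(d1)
  expect_equal(back, sim1$counts, ignore_attr = FALSE)
})
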