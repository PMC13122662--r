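test_that("identical configuration and seed give bit-identical output", {
  cfg <- sim_config(n_cells_per_state = small_sizes, n_genes = 400, seed = 7)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_tags(a$truth, cfg), simulate_tags(b$truth, cfg))
})

test_that("truth table and matrices agree in dimensions and barcodes", {
  cfg <- sim_config(n_cells_per_state = small_sizes, n_genes = 400, seed = 2)
  sim <- simulate_counts(cfg)
  expect_equal(ncol(sim$counts), sum(small_sizes))
  expect_identical(colnames(sim$counts), sim$truth$barcode)
  expect_equal(nrow(sim$counts), 400)
  tags <- simulate_tags(sim$truth, cfg)
  expect_identical(colnames(tags), sim$truth$barcode)
  singlets <- !sim$truth$is_doublet
  expect_true(all(sim$truth$state[singlets] %in%
                    c("primed", "bridge", "intermediate_A", "intermediate_B",
                      "naive", "ectoderm", "mesoderm")))
  expect_true(all(sim$truth$hashtag[singlets] %in% paste0("HT", 1:4)))
  expect_true(all(sim$truth$latent_time >= 0 & sim$truth$latent_time <= 1))
})

test_that("configuration validation rejects bad inputs", {
  expect_error(sim_config(program_sizes = setNames(rep(400L, 7),
    c("pluripotency", "naive", "diff_suppressive", "neural",
      "metallothionein", "mesoderm", "housekeeping")), n_genes = 500),
    "exceeds n_genes")
  expect_error(sim_config(doublet_rate = 0.7), "doublet_rate")
  expect_error(sim_config(tag_background_fraction = 0.9), "background")
  expect_error(sim_config(nb_dispersion = -1), "dispersion")
})

test_that("zero signal makes states exchangeable (Poisson limit)", {
  cfg <- sim_config(n_cells_per_state = small_sizes, n_genes = 300,
                    program_sizes = small_programs, program_logfc = 0, nb_dispersion = 1e8,
                    branch_noise_sd = 0, doublet_rate = 0, seed = 3)
  sim <- simulate_counts(cfg)
  totals <- Matrix::colSums(sim$counts)
  by_state <- split(totals, sim$truth$state)
  overall <- mean(totals)
  for (s in names(by_state)) {
    se <- sd(by_state[[s]]) / sqrt(length(by_state[[s]]))
    expect_lt(abs(mean(by_state[[s]]) - overall), 4 * se + 1e-9)
  }
})

test_that("program fold change matches the stated NB model", {
  cfg <- sim_config(n_cells_per_state = c(primed = 500, naive = 500),
                    n_genes = 400, program_logfc = 3, base_mean = 0.1,
                    branch_noise_sd = 0, doublet_rate = 0, seed = 11)
  sim <- simulate_counts(cfg)
  naive_genes <- grep("^naive_", rownames(sim$counts))
  is_naive <- sim$truth$state == "naive"
  obs_naive <- mean(as.matrix(sim$counts[naive_genes, is_naive]))
  obs_primed <- mean(as.matrix(sim$counts[naive_genes, !is_naive]))
  ## sample-mean oracle: primed cells have zero naive activation, naive
  ## cells follow the documented ramp 0.65 + 0.35 * (t - 0.7) / 0.3
  act <- 0.65 + 0.35 * (sim$truth$latent_time[is_naive] - 0.7) / 0.3
  expected_ratio <- mean(exp(3 * act))
  expect_lt(abs(obs_naive / obs_primed - expected_ratio),
            0.15 * expected_ratio)
  expect_gt(obs_naive / obs_primed, exp(3 * 0.65))
})

test_that("inject_doublets sums parent columns and preserves totals", {
  cfg <- sim_config(n_cells_per_state = small_sizes, n_genes = 300,
                    program_sizes = small_programs, doublet_rate = 0,
                    seed = 5)
  sim <- simulate_counts(cfg)
  out0 <- inject_doublets(sim$counts, sim$truth, rate = 0)
  expect_identical(as.matrix(out0$counts), as.matrix(sim$counts))
  out <- inject_doublets(sim$counts, sim$truth, rate = 0.1, seed = 9)
  d <- sum(out$truth$is_doublet)
  expect_equal(d, floor(0.1 * ncol(sim$counts)))
  expect_equal(ncol(out$counts), ncol(sim$counts) - d)
  dbl <- out$truth[out$truth$is_doublet, ]
  for (i in seq_len(nrow(dbl))) {
    expected <- sim$counts[, dbl$parent1[i]] + sim$counts[, dbl$parent2[i]]
    expect_equal(as.numeric(out$counts[, dbl$barcode[i]]),
                 as.numeric(expected))
  }
  expect_error(inject_doublets(sim$counts, sim$truth, rate = 0.9), "rate")
})

test_that("doublet totals stochastically dominate singlet totals", {
  cfg <- sim_config(n_cells_per_state = c(primed = 500, naive = 500),
                    n_genes = 300, program_sizes = small_programs,
                    doublet_rate = 0.1, seed = 13)
  sim <- simulate_counts(cfg)
  totals <- Matrix::colSums(sim$counts)
  p <- wilcox.test(totals[sim$truth$is_doublet],
                   totals[!sim$truth$is_doublet],
                   alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("hashtag reads land on exactly one hashtag without background", {
  cfg <- sim_config(n_cells_per_state = small_sizes,
                    tag_background_fraction = 0, doublet_rate = 0,
                    n_genes = 300, program_sizes = small_programs, seed = 4)
  sim <- simulate_counts(cfg)
  tags <- simulate_tags(sim$truth, cfg)
  expect_true(all(colSums(tags > 0) == 1))
  own <- tags[cbind(match(sim$truth$hashtag, rownames(tags)),
                    seq_len(ncol(tags)))]
  expect_true(all(own > 0))
})

test_that("heavy hashtag background degrades demultiplexing accuracy", {
  ## two hashtags: at background 0.5 a singlet's reads split evenly
  ## between both tags, so assignment degenerates to a coin flip
  sizes <- c(primed = 300, naive = 300)
  acc <- sapply(c(0.05, 0.5), function(bg) {
    cfg <- sim_config(n_cells_per_state = sizes, n_genes = 200,
                      program_sizes = small_programs,
                      tag_background_fraction = bg, doublet_rate = 0,
                      tag_depth = c(HT1 = 80, HT3 = 80), seed = 21)
    sim <- simulate_counts(cfg)
    tags <- simulate_tags(sim$truth, cfg)
    a <- assign_tags(normalize_tags(tags))
    mean(a$hashtag == sim$truth$hashtag, na.rm = TRUE)
  })
  expect_gt(acc[1], acc[2])
})

test_that("discrete noise-free states are recovered exactly by CLARA", {
  cfg <- sim_config(n_cells_per_state = c(primed = 100, naive = 100,
                                          ectoderm = 100, mesoderm = 100),
                    program_logfc = 6, nb_dispersion = 1e6,
                    branch_noise_sd = 0, doublet_rate = 0,
                    discrete_states = TRUE, seed = 5)
  sim <- simulate_counts(cfg)
  pre <- preprocess_counts(sim$counts, min_counts_per_cell = 0)
  emb <- embed_cells(pre)
  run <- clara_run(emb, 4, ensemble_config(), seed = 9)
  ## adjusted Rand index of 1 means the unordered partitions coincide
  tab <- table(run$labels, sim$truth$state)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("simulated datasets round-trip through disk", {
  cfg <- sim_config(n_cells_per_state = c(primed = 30, naive = 30),
                    n_genes = 200, program_sizes = small_programs, seed = 8)
  sim <- simulate_counts(cfg)
  tags <- simulate_tags(sim$truth, cfg)
  dir <- withr::local_tempdir()
  write_sim_dataset(sim, tags, cfg, dir)
  back <- read_count_matrix(file.path(dir, "counts.mtx"))
  expect_identical(as.matrix(back), as.matrix(sim$counts))
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), nrow(sim$truth))
  cfg_back <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg_back$n_genes, 200)
})
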