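test_that("sim_config validates proportions, replicates and dispersion", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_genes = 0), "zero genes")
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(sim_config(dispersion = 0), "dispersion")
  bad <- c(additive = 0.5, high_dom = 0.1, low_dom = 0.1, overdominant = 0.1,
           underdominant = 0.1, pav_I = 0.1, pav_II = 0.1, pav_III = 0.1,
           pav_IV = 0.1)  # sums to 1.3
  expect_error(sim_config(mode_proportions = bad), "simplex")
  expect_error(sim_config(response_coupling = "dominance"), "shared_modes")
})

test_that("generating means obey the mode construction rules exactly", {
  cfg <- sim_config(n_genes = 300, seed = 21)
  sim <- simulate_trios(cfg)
  tr <- sim$truth
  mu <- tr$means
  D <- cfg$effect_log2fc
  ww <- mu[mu$condition == "WW", ]
  wide <- reshape(ww[, c("gene_id", "trio_id", "role", "mu")],
                  idvar = c("gene_id", "trio_id"), timevar = "role",
                  direction = "wide")
  names(wide) <- sub("^mu\\.", "", names(wide))
  key <- paste(tr$genes$gene_id, tr$genes$trio_id)
  wide$mode <- tr$genes$mode[match(paste(wide$gene_id, wide$trio_id), key)]
  with(subset(wide, mode == "additive"), {
    expect_equal(hybrid, (parent1 + parent2) / 2)
    expect_equal(pmax(parent1, parent2) / pmin(parent1, parent2),
                 rep(2^D, length(hybrid)))
  })
  with(subset(wide, mode == "high_dom"),
       expect_equal(hybrid, pmax(parent1, parent2)))
  with(subset(wide, mode == "low_dom"),
       expect_equal(hybrid, pmin(parent1, parent2)))
  with(subset(wide, mode == "overdominant"), {
    expect_equal(parent1, parent2)
    expect_equal(hybrid, pmax(parent1, parent2) * 2^D)
  })
  with(subset(wide, mode == "underdominant"),
       expect_equal(hybrid, pmin(parent1, parent2) / 2^D))
  with(subset(wide, mode == "pav_I"), {
    expect_true(all(hybrid == 0))
    expect_true(all(parent1 > 0 & parent2 > 0))
  })
  with(subset(wide, mode == "pav_II"), {
    expect_true(all(hybrid == 0))
    expect_true(all(xor(parent1 > 0, parent2 > 0)))
  })
  with(subset(wide, mode == "pav_III"),
       expect_true(all(hybrid > 0 & parent1 == 0 & parent2 == 0)))
  with(subset(wide, mode == "pav_IV"), {
    expect_true(all(hybrid > 0))
    expect_true(all(xor(parent1 > 0, parent2 > 0)))
  })
})

test_that("condition response scales WD means and reset reverts RW means", {
  cfg <- sim_config(n_genes = 200, seed = 22)
  sim <- simulate_trios(cfg)
  mu <- sim$truth$means
  g <- sim$truth$genes[sim$truth$genes$trio_id == "AB", ]
  D <- 2^cfg$effect_log2fc
  wide <- reshape(mu[mu$trio_id == "AB" & mu$role == "hybrid",
                     c("gene_id", "condition", "mu")],
                  idvar = "gene_id", timevar = "condition",
                  direction = "wide")
  names(wide) <- sub("^mu\\.", "", names(wide))
  wide <- merge(wide, g[, c("gene_id", "mode", "response", "reset")])
  expr <- wide[wide$WW > 0, ]
  up <- expr[expr$response == "up", ]
  expect_equal(up$WD, up$WW * D)
  down <- expr[expr$response == "down", ]
  expect_equal(down$WD, down$WW / D)
  nul <- expr[expr$response == "null", ]
  expect_equal(nul$WD, nul$WW)
  expect_equal(expr$RW[expr$reset], expr$WW[expr$reset])
  persist <- expr[!expr$reset & expr$response != "null", ]
  expect_equal(persist$RW, persist$WD)
})

test_that("simulation is deterministic given seed and PAV cells are all-zero", {
  cfg <- sim_config(n_genes = 100, seed = 9)
  s1 <- simulate_trios(cfg)
  s2 <- simulate_trios(cfg)
  expect_identical(s1$es$counts, s2$es$counts)
  expect_identical(s1$truth$genes, s2$truth$genes)
  s3 <- simulate_trios(sim_config(n_genes = 100, seed = 10))
  expect_false(identical(s1$es$counts, s3$es$counts))

  # mean 0 => count 0 in every replicate
  mu <- s1$truth$means
  zero <- mu[mu$mu == 0, ]
  sh <- s1$es$sheet
  for (i in seq_len(nrow(zero))) {
    ids <- sh$sample_id[sh$trio_id == zero$trio_id[i] &
                        sh$role == zero$role[i] &
                        sh$condition == zero$condition[i]]
    expect_true(all(s1$es$counts[zero$gene_id[i], ids] == 0))
  }
})

test_that("counts match the NB(mu, alpha) moments", {
  cfg <- sim_config(n_genes = 2000, seed = 31)
  sim <- simulate_trios(cfg)
  mu <- sim$truth$means
  sh <- sim$es$sheet
  s <- sim$truth$lib_factors
  # expected mean per gene x sample cell
  idx <- match(paste(mu$trio_id, mu$role, mu$condition),
               paste(sh$trio_id, sh$role, sh$condition))
  m <- matrix(0, nrow(sim$es$counts), nrow(sh),
              dimnames = dimnames(sim$es$counts))
  for (j in seq_len(nrow(sh))) {
    sub <- mu[mu$trio_id == sh$trio_id[j] & mu$role == sh$role[j] &
              mu$condition == sh$condition[j], ]
    m[sub$gene_id, j] <- sub$mu * s[[sh$sample_id[j]]]
  }
  pos <- m > 0
  z <- (sim$es$counts[pos] - m[pos]) /
    sqrt(m[pos] + cfg$dispersion * m[pos]^2)
  expect_lt(abs(mean(z)), 0.02)
  expect_lt(abs(stats::var(z) - 1), 0.05)
})

test_that("sample means converge to the generating means at many replicates", {
  cfg <- sim_config(n_genes = 50, n_replicates = 200, dispersion = 1e-4,
                    conditions = "WW",
                    trios = list(T1 = c(hybrid = "H", parent1 = "P1",
                                        parent2 = "P2")),
                    seed = 4)
  sim <- simulate_trios(cfg)
  mu <- sim$truth$means
  sh <- sim$es$sheet
  s <- sim$truth$lib_factors
  rel_err <- c()
  for (role in c("hybrid", "parent1", "parent2")) {
    ids <- sh$sample_id[sh$role == role]
    expected <- mu$mu[mu$role == role][match(rownames(sim$es$counts),
                                             mu$gene_id[mu$role == role])]
    scaled <- sweep(sim$es$counts[, ids], 2, s[ids], "/")
    obs <- rowMeans(scaled)
    keep <- expected > 0
    rel_err <- c(rel_err, abs(obs[keep] - expected[keep]) / expected[keep])
  }
  expect_lt(mean(rel_err), 0.02)
  expect_lt(max(rel_err), 0.10)
})

test_that("simulated phenotypes honour means, sd and replication rules", {
  spec <- list(list(trait = "EL",
                    genotypes = c(hybrid = "AB", parent1 = "AA", parent2 = "BB"),
                    means = list(WW = c(hybrid = 12, parent1 = 10, parent2 = 6)),
                    sd = 0, n_rep = 3))
  ph <- simulate_phenotypes(spec, seed = 1)
  expect_equal(ph$value[ph$genotype_id == "AB"], rep(12, 3))
  expect_equal(ph$value[ph$genotype_id == "BB"], rep(6, 3))

  spec[[1]]$n_rep <- 1
  expect_error(simulate_phenotypes(spec, seed = 1), "n_rep")
  spec[[1]]$n_rep <- 3
  spec[[1]]$means$WW[["hybrid"]] <- -2
  expect_error(simulate_phenotypes(spec, seed = 1), "non-positive")

  # downstream MPH on generating means 12/10/6 recovers ~50% with noise
  spec[[1]]$means$WW[["hybrid"]] <- 12
  spec[[1]]$sd <- 0.5
  spec[[1]]$n_rep <- 5
  ph2 <- simulate_phenotypes(spec, seed = 7)
  h <- heterosis_indices(ph2, spec[[1]]$genotypes, "WW", "EL")
  expect_lt(abs(h$MPH_pct - 50), 5)
})

test_that("simulated annotation packs enriched terms and supports degenerate inputs", {
  sim <- simulate_trios(sim_config(n_genes = 400, seed = 17))
  am0 <- simulate_annotation(sim$truth, n_terms = 0, seed = 1)
  expect_length(am0$terms, 0)

  am <- simulate_annotation(sim$truth, n_terms = 30, enriched_fraction = 0.3,
                            seed = 5)
  rec <- attr(am, "sim_truth")
  expect_equal(nrow(rec), 30)
  expect_equal(sum(rec$class != "uniform"), 9)

  # a term packed with response:up genes is strongly enriched downstream
  up_genes <- unique(sim$truth$genes$gene_id[sim$truth$genes$response == "up"])
  packed <- rec$term_id[rec$class == "response:up"]
  if (length(packed)) {
    universe <- unique(sim$truth$genes$gene_id)
    res <- enrich(up_genes, am, universe)
    expect_lt(res$p_value[res$term_id == packed[1]], 0.05)
  }
})
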