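test_that("expressed_flag thresholds replicates correctly", {
  expect_false(expressed_flag(c(0, 0, 0)))
  expect_true(expressed_flag(c(5, 3, 0.2)))
  expect_false(expressed_flag(c(1.0, 0.9, 0.9)))  # only one rep reaches tau
  expect_true(expressed_flag(c(1.0, 1.0, 0)))
  expect_true(expressed_flag(c(0.5, 0.5, 0.5), tau = 0.5, min_reps = 3))
})

test_that("classify_pav reproduces the presence/absence truth table", {
  combos <- expand.grid(f1 = c(TRUE, FALSE), p1 = c(TRUE, FALSE),
                        p2 = c(TRUE, FALSE))
  got <- classify_pav(combos$f1, combos$p1, combos$p2)
  want <- mapply(pav_oracle, combos$f1, combos$p1, combos$p2)
  expect_identical(got, unname(want))
  # spot checks straight from the definitions
  expect_identical(classify_pav(FALSE, TRUE, TRUE), "I")
  expect_identical(classify_pav(TRUE, FALSE, FALSE), "III")
  expect_identical(classify_pav(FALSE, FALSE, FALSE), NA_character_)
  # informative rows partition into exactly one type each
  inf <- !is.na(got)
  expect_equal(sum(inf), 7L)
  expect_setequal(got[inf], c("I", "II", "II", "III", "IV", "IV", "V"))
})

test_that("classify_mode matches an independently coded rule table on all inputs", {
  grid <- expand.grid(f1_vs_p1 = tri_states, f1_vs_p2 = tri_states,
                      f1_vs_mpv = tri_states, p1_vs_p2 = tri_states,
                      stringsAsFactors = FALSE)
  got <- classify_mode(grid$f1_vs_p1, grid$f1_vs_p2, grid$f1_vs_mpv,
                       grid$p1_vs_p2)
  want <- mapply(mode_oracle, grid$f1_vs_p1, grid$f1_vs_p2, grid$f1_vs_mpv,
                 grid$p1_vs_p2)
  expect_identical(got, unname(want))
  # every input maps to exactly one label
  expect_true(all(got %in% c("additive", "overdominant", "underdominant",
                             "high_dominance", "low_dominance", "other")))
  # headline rows
  expect_identical(classify_mode("higher", "higher", "higher", "equal"),
                   "overdominant")
  expect_identical(classify_mode("equal", "lower", "lower", "higher"),
                   "high_dominance")
  expect_identical(classify_mode("lower", "higher", "equal", "lower"),
                   "additive")
  expect_error(classify_mode("big", "higher", "higher", "equal"), "tri-state")
})

test_that("midparent test is null for additive genes and detects large shifts", {
  # hybrid replicates equal to the parent-pair means => ratio exactly 0
  counts <- rbind(g1 = c(40, 60, 50, 30, 50, 40, 50, 70, 60),
                  g2 = c(400, 480, 420, 60, 50, 40, 40, 70, 60))
  colnames(counts) <- c("H_WW_1", "H_WW_2", "H_WW_3", "P1_WW_1", "P1_WW_2",
                        "P1_WW_3", "P2_WW_1", "P2_WW_2", "P2_WW_3")
  es <- toy_es(counts)
  res <- midparent_test(es, "T1", "WW", alpha_mode = "fixed",
                        alpha_fixed = 0.05, sf = rep(1, 9))
  expect_equal(res$log2fc[res$gene_id == "g1"], 0)
  expect_gt(res$p_value[res$gene_id == "g1"], 0.9)
  # g2 hybrid is ~8x the midparent
  expect_gt(res$log2fc[res$gene_id == "g2"], 2)
  expect_lt(res$p_value[res$gene_id == "g2"], 0.01)

  # Monte-Carlo: strong overdominance is consistently flagged
  cfg <- sim_config(n_genes = 150, seed = 8,
                    trios = list(T1 = c(hybrid = "H", parent1 = "P1",
                                        parent2 = "P2")),
                    conditions = "WW",
                    mode_proportions = c(additive = 0.8, high_dom = 0,
                                         low_dom = 0, overdominant = 0.2,
                                         underdominant = 0, pav_I = 0,
                                         pav_II = 0, pav_III = 0, pav_IV = 0),
                    effect_log2fc = 3)
  sim <- simulate_trios(cfg)
  # true library factors isolate the mid-parent machinery from the
  # normalisation step (with an 8-fold parental split in most genes,
  # median-of-ratios has no stable non-DE majority between roles)
  mp <- midparent_test(sim$es, "T1", "WW", sf = sim$truth$lib_factors)
  mp <- call_de(mp)
  truth <- sim$truth$genes
  over <- truth$gene_id[truth$mode == "overdominant"]
  add <- truth$gene_id[truth$mode == "additive"]
  expect_gt(mean(mp$call[mp$gene_id %in% over] == "up"), 0.9)
  expect_gt(mean(mp$call[mp$gene_id %in% add] == "ns"), 0.9)
})

test_that("classify_all recovers a pure-additive simulation and partitions genes", {
  cfg <- sim_config(n_genes = 500, seed = 19,
                    mode_proportions = c(additive = 1, high_dom = 0,
                                         low_dom = 0, overdominant = 0,
                                         underdominant = 0, pav_I = 0,
                                         pav_II = 0, pav_III = 0, pav_IV = 0),
                    conditions = "WW")
  sim <- simulate_trios(cfg)
  calls <- classify_all(sim$es)
  expect_gt(mean(calls$mode[calls$pav_type == "V"] == "additive"), 0.9)

  # partition property: every gene gets exactly one label per trio x condition
  counts <- table(calls$trio_id, calls$condition)
  expect_true(all(counts == nrow(sim$es$counts)))
  expect_true(all(calls$pav_type %in% c("I", "II", "III", "IV", "V",
                                        "not_detected")))
  # mode assigned iff type V
  expect_true(all((calls$mode != "not_applicable") == (calls$pav_type == "V")))
})

test_that("PAV-silenced simulation genes are typed I-IV, never V", {
  cfg <- sim_config(n_genes = 400, seed = 23,
                    mode_proportions = c(additive = 0.2, high_dom = 0,
                                         low_dom = 0, overdominant = 0,
                                         underdominant = 0, pav_I = 0.2,
                                         pav_II = 0.2, pav_III = 0.2,
                                         pav_IV = 0.2),
                    conditions = "WW")
  sim <- simulate_trios(cfg)
  calls <- classify_all(sim$es)
  truth <- sim$truth$genes
  key <- paste(calls$gene_id, calls$trio_id)
  tkey <- paste(truth$gene_id, truth$trio_id)
  tmode <- truth$mode[match(key, tkey)]
  for (lab in c("pav_I", "pav_II", "pav_III", "pav_IV")) {
    roman <- sub("pav_", "", lab)
    expect_gt(mean(calls$pav_type[tmode == lab] == roman), 0.95)
    expect_false(any(calls$pav_type[tmode == lab] == "V"))
  }
})

test_that("merged overdominant set is the disjoint union of type III and mode overdominant", {
  calls <- data.frame(
    gene_id = paste0("g", 1:6), trio_id = "T1", condition = "WD",
    pav_type = c("III", "III", "V", "V", "V", "I"),
    mode = c("not_applicable", "not_applicable", "overdominant",
             "overdominant", "additive", "not_applicable"),
    stringsAsFactors = FALSE)
  mo <- merged_overdominant(calls)
  expect_setequal(mo[["T1.WD"]], c("g1", "g2", "g3", "g4"))
  # III excludes V, so the union size is the exact sum
  expect_equal(length(mo[["T1.WD"]]), 2 + 2)
  # empty type III still returns the overdominant genes
  calls2 <- calls[calls$pav_type == "V", ]
  expect_setequal(merged_overdominant(calls2)[["T1.WD"]], c("g3", "g4"))
})

test_that("swapping parent labels preserves symmetric calls and maps dominance", {
  cfg <- sim_config(n_genes = 500, seed = 29, conditions = "WW",
                    trios = list(T1 = c(hybrid = "H", parent1 = "P1",
                                        parent2 = "P2")))
  sim <- simulate_trios(cfg)
  calls <- classify_all(sim$es)

  sheet_sw <- sim$es$sheet
  sheet_sw$role[sheet_sw$role == "parent1"] <- "tmp"
  sheet_sw$role[sheet_sw$role == "parent2"] <- "parent1"
  sheet_sw$role[sheet_sw$role == "tmp"] <- "parent2"
  es_sw <- trio_expression_set(sim$es$counts, sheet_sw)
  calls_sw <- classify_all(es_sw)
  calls_sw <- calls_sw[match(paste(calls$gene_id, calls$condition),
                             paste(calls_sw$gene_id, calls_sw$condition)), ]
  sym <- c("additive", "overdominant", "underdominant")
  for (lab in sym)
    expect_identical(calls$gene_id[calls$mode == lab],
                     calls_sw$gene_id[calls_sw$mode == lab])
  expect_identical(calls$gene_id[calls$mode == "high_dominance"],
                   calls_sw$gene_id[calls_sw$mode == "high_dominance"])
  expect_identical(calls$gene_id[calls$mode == "low_dominance"],
                   calls_sw$gene_id[calls_sw$mode == "low_dominance"])
  expect_identical(calls$pav_type, calls_sw$pav_type)
})

test_that("mode recovery degrades as the effect size shrinks", {
  diag_sens <- function(lfc) {
    cfg <- sim_config(n_genes = 600, seed = 37, conditions = "WW",
                      effect_log2fc = lfc,
                      trios = list(T1 = c(hybrid = "H", parent1 = "P1",
                                          parent2 = "P2")))
    sim <- simulate_trios(cfg)
    calls <- classify_all(sim$es)
    sens <- mode_confusion(calls, sim$truth, "WW")$sensitivity
    mean(sens[c("overdominant", "underdominant")])
  }
  s_strong <- diag_sens(2)
  s_weak <- diag_sens(1)
  expect_gt(s_strong, s_weak)
  expect_gt(s_strong, 0.85)
})
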