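# Generators: determinism, planted-structure recovery, null behaviour, and
# config validation.

test_that("sc generator is deterministic and plants the requested structure", {
  g <- genes_n(500)
  cfg <- sc_config(n_genes = 500, n_malignant = 300, n_immune = 100,
                   n_stromal = 50, corr_genes = g[1:12], corr_rho = 0.6,
                   up_genes = g[21:30], up_delta = 1.0, seed = 101)
  d1 <- make_sc_dataset(cfg)
  d2 <- make_sc_dataset(cfg)
  expect_identical(d1$expr, d2$expr)
  expect_identical(d1$cell_meta, d2$cell_meta)
  mal <- d1$cell_meta$cell_type == "malignant"
  # planted correlation lands near the target
  rhos <- vapply(g[1:12], function(gn)
    cor(d1$expr[gn, mal], d1$truth$score, method = "spearman"), 0)
  expect_true(all(abs(rhos - 0.6) < 0.1))
  # planted upregulation shows up as a malignant mean shift near delta
  shift <- rowMeans(d1$expr[g[21:30], mal]) - rowMeans(d1$expr[g[21:30], !mal])
  expect_true(all(abs(shift - 1.0) < 0.3))
})

test_that("null sc configuration yields empty downstream candidate sets", {
  cfg <- sc_config(n_genes = 300, n_malignant = 150, n_immune = 100,
                   n_stromal = 50, seed = 77)
  d <- make_sc_dataset(cfg)
  mal <- d$cell_meta$cell_type == "malignant"
  de <- malignant_de_screen(d$expr, d$cell_meta$cell_type)
  expect_length(de$Gy, 0)
  scr <- ansd_correlation_screen(d$expr[, mal],
                                 withr::with_seed(1, rnorm(sum(mal))))
  # a random score: rho > 0.3 at n = 150 is essentially impossible
  expect_length(scr$Gx, 0)
})

test_that("sc generator validates planted gene lists", {
  expect_error(make_sc_dataset(sc_config(n_genes = 10, corr_genes = "NOPE")),
               "outside universe")
  expect_error(sc_config(up_genes = "G0001", up_delta = -1), "up_delta")
})

test_that("ici cohort generator encodes labels, batches and survival consistently", {
  cfg <- ici_config(batch_sizes = c(60L, 80L), n_genes = 100,
                    effect_d = 0, seed = 5)
  co <- make_ici_cohort(cfg)
  expect_identical(co$expr, make_ici_cohort(cfg)$expr)
  expect_equal(ncol(co$expr), 140)
  expect_setequal(unique(co$clinical$recist), c("CR", "PR", "SD", "PD"))
  expect_equal(encode_response(co$clinical$recist), co$truth$responder)
  expect_true(all(co$clinical$os_time > 0))
  # planted batch shift is visible pre-correction and gone post-correction
  cfg2 <- ici_config(batch_sizes = c(60L, 80L), n_genes = 100,
                     batch_shift = c(0, 2), effect_d = 0, seed = 6)
  co2 <- make_ici_cohort(cfg2)
  gap <- rowMeans(co2$expr[, co2$clinical$batch == "batch2"]) -
    rowMeans(co2$expr[, co2$clinical$batch == "batch1"])
  expect_equal(mean(gap), 2, tolerance = 0.1)
  corr <- correct_batches(co2$expr, co2$clinical$batch)
  gap2 <- rowMeans(corr[, co2$clinical$batch == "batch2"]) -
    rowMeans(corr[, co2$clinical$batch == "batch1"])
  expect_lt(max(abs(gap2)), 1e-8)
})

test_that("crispr generator plants resistance genes and respects the null", {
  cfg <- crispr_config(n_genes = 5000, n_datasets = 10, shift = -3, seed = 9)
  scr <- make_crispr_screens(cfg)
  expect_identical(scr$table, make_crispr_screens(cfg)$table)
  rk <- rank_by_mean_z(zscore_normalize(scr$table))
  top <- rk$gene[seq_len(floor(0.02 * nrow(rk)))]
  expect_gte(mean(scr$truth$resistance_genes %in% top), 0.9)
  # null: planted list is an arbitrary subset; ranks uniform (KS test)
  cfg0 <- crispr_config(n_genes = 2000, n_datasets = 8, shift = -1e-9, seed = 10)
  scr0 <- make_crispr_screens(cfg0)
  rk0 <- rank_by_mean_z(zscore_normalize(scr0$table))
  pos <- match(scr0$truth$resistance_genes, rk0$gene) / nrow(rk0)
  expect_gt(suppressWarnings(ks.test(pos, "punif"))$p.value, 0.01)
  expect_error(crispr_config(n_datasets = 1), ">= 2 datasets")
  expect_error(crispr_config(shift = 0.5), "negative")
})

test_that("maf generator reproduces per-cluster mutation probabilities", {
  probs <- rbind(ALWAYS = c(A = 1, B = 0.5), NEVER = c(A = 0, B = 0),
                 MID = c(A = 0.58, B = 0.2))
  cfg <- maf_config(cluster_sizes = c(A = 200L, B = 100L),
                    mutation_probs = probs, seed = 12)
  m <- make_maf(cfg)
  expect_identical(m$maf, make_maf(cfg)$maf)
  fr <- mutation_frequency(m$maf, m$truth$clusters, exclude_classes = character())
  expect_equal(fr$frequency[fr$gene == "ALWAYS" & fr$cluster == "A"], 1.0)
  expect_false("NEVER" %in% m$maf$Hugo_Symbol)
  expect_equal(fr$frequency[fr$gene == "MID" & fr$cluster == "A"], 0.58,
               tolerance = 0.07 / 0.58)
  expect_error(maf_config(mutation_probs = probs * 3), "\\[0, 1\\]")
})

test_that("infiltration generator couples named rows at the target rho", {
  co <- make_ici_cohort(ici_config(batch_sizes = c(100L, 100L), n_genes = 50,
                                   seed = 2))
  inf <- make_infiltration(co$expr, coupled_genes = c("G0001", "G0002"),
                           rho = 0.35, n_celltypes = 10, seed = 3)
  expect_identical(inf$abundance,
                   make_infiltration(co$expr, c("G0001", "G0002"), 0.35,
                                     n_celltypes = 10, seed = 3)$abundance)
  r <- cor(inf$abundance["celltype_01", ], co$expr["G0001", ],
           method = "spearman")
  expect_lt(abs(r - 0.35), 0.15)
  expect_gt(r, 0)
  expect_error(make_infiltration(co$expr, "NOPE"), "absent")
})
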