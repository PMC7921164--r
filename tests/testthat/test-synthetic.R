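test_that("truth generation is deterministic and respects constant parameters", {
  suite <- benchmark_suite()
  A <- suite$A
  tr1 <- generate_truth(A, n_t = 10, refine = 5)
  tr2 <- generate_truth(A, n_t = 10, refine = 5)
  expect_identical(tr1$states, tr2$states) # no randomness in the truth
  # constant parameters: output equals the fixed-parameter simulation
  x0 <- steady_state(A$model, A$p_base)
  sim <- simulate_model(A$model, x0, A$p_base, tr1$times)
  expect_equal(tr1$states, t(sim$states), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("step scenarios settle onto the fixed-parameter steady states", {
  m <- toy_lipid_model()
  p <- toy_p_base(m)
  sc <- synthetic_scenario("step", m, p,
                           param_traj = list(k_upt = traj_step(2, 3)),
                           observed = names(m$outputs), t_end = 60,
                           schedule = c(0, 2, 10, 30, 60), cv = 0)
  tr <- generate_truth(sc, n_t = 60, refine = 10)
  p_post <- p; p_post[["k_upt"]] <- 3 * p[["k_upt"]]
  ss_pre <- steady_state(m, p)
  ss_post <- steady_state(m, p_post)
  expect_equal(unname(tr$states[, 1]), unname(ss_pre), tolerance = 0.01)
  expect_equal(unname(tr$states[, ncol(tr$states)]), unname(ss_post),
               tolerance = 0.01)
})

test_that("observations follow the stated noise model", {
  suite <- benchmark_suite(cv = 0)
  tr <- generate_truth(suite$A, n_t = 10, refine = 5)
  # CV = 0: means equal the truth, SDs are 0
  obs0 <- generate_observations(tr, seed = 1)
  sel <- obs0$observable == "tg_plasma"
  expect_equal(obs0$mean[sel],
               stats::approx(tr$times, tr$outputs["tg_plasma", ],
                             xout = obs0$time[sel])$y,
               tolerance = 1e-9)
  expect_true(all(obs0$sd == 0))
  # seeded determinism
  obs1 <- generate_observations(tr, seed = 7, cv = 0.1)
  obs2 <- generate_observations(tr, seed = 7, cv = 0.1)
  expect_identical(obs1, obs2)
  # recorded means center on the truth within standard error:
  # 200 seeds x N = 6 replicates at CV = 0.1
  v <- tr$outputs["tg_plasma", 1]
  means <- vapply(1:200, function(s) {
    o <- generate_observations(tr, seed = s, cv = 0.1)
    o$mean[o$observable == "tg_plasma" & o$time == 0]
  }, 0)
  expect_lt(abs(mean(means) - v), 3 * 0.1 * v / sqrt(6 * 200))
  # generated datasets validate against the reader schema unchanged
  path <- withr::local_tempfile(fileext = ".csv")
  write_longitudinal_csv(obs1, path)
  expect_equal(tibble::as_tibble(read_longitudinal_csv(path)),
               tibble::as_tibble(obs1))
})

test_that("gene profiles correlate with their parameters as designed", {
  suite <- benchmark_suite()
  B <- suite$B
  # zero noise, zero lag, positive sign: correlation exactly 1
  B0 <- B
  B0$gene_design$cv <- 0
  g0 <- generate_gene_profiles(B0, seed = 1)
  sched <- B$schedule
  for (gene in c("g_upt", "g_dnl1")) {
    par <- B$gene_design$parameter[B$gene_design$gene == gene]
    truthp <- B$param_traj[[par]](sched)
    prof <- g0$mean[g0$observable == gene]
    expect_equal(pearson(prof, truthp), 1, tolerance = 1e-9)
    expect_equal(prof[1], 1) # relative expression, normalized at t = 0
  }
  # negative sign flips the correlation to -1
  Bn <- B0
  Bn$gene_design$sign[Bn$gene_design$gene == "g_upt"] <- -1
  Bn$gene_design$strength[Bn$gene_design$gene == "g_upt"] <- 0.3
  gn <- generate_gene_profiles(Bn, seed = 1)
  prof <- gn$mean[gn$observable == "g_upt"]
  expect_equal(pearson(prof, B$param_traj$k_upt(sched)), -1, tolerance = 1e-9)
  # a decoupled gene contradicts its parameter the same way
  Bd <- B0
  Bd$gene_design$decoupled[Bd$gene_design$gene == "g_upt"] <- TRUE
  Bd$gene_design$strength[Bd$gene_design$gene == "g_upt"] <- 0.3
  gd <- generate_gene_profiles(Bd, seed = 1)
  expect_equal(pearson(gd$mean[gd$observable == "g_upt"],
                       B$param_traj$k_upt(sched)), -1, tolerance = 1e-9)
  # with noise, coupled genes outrank flat distractors in correlation with
  # truth in the vast majority of seeded draws
  hits <- 0
  for (s in 1:100) {
    g <- generate_gene_profiles(B, seed = s)
    r_coupled <- abs(pearson(g$mean[g$observable == "g_upt"],
                             B$param_traj$k_upt(sched)))
    r_flat <- abs(pearson(g$mean[g$observable == "g_flat1"],
                          B$param_traj$k_upt(sched)))
    hits <- hits + (r_coupled > r_flat)
  }
  expect_gte(hits, 95)
})

test_that("benchmark scenarios are coherent with the pipeline readers", {
  suite <- benchmark_suite()
  expect_named(suite, c("A", "B", "C"))
  dir <- withr::local_tempdir()
  write_scenario(suite$B, dir, seed = 3, n_t = 7, refine = 5)
  # round trip through the package's own readers
  m <- read_model_json(file.path(dir, "model.json"))
  expect_equal(m$stoichiometry, suite$B$model$stoichiometry)
  met <- read_longitudinal_csv(file.path(dir, "metabolic.csv"))
  expect_true(all(met$kind == "metabolic"))
  cpl <- read_coupling_csv(file.path(dir, "coupling.csv"))
  expect_setequal(cpl$gene, c("g_upt", "g_dnl1", "g_dnl2", "g_cat",
                              "g_load", "g_sec"))
  truth <- readr::read_csv(file.path(dir, "truth.csv"), show_col_types = FALSE)
  expect_setequal(unique(truth$kind), c("parameter", "state", "flux", "output"))
})

test_that("the latent-pool scenario is non-identifiable without the split anchor", {
  # two baselines with different cytosol/ER splits fit the summed data
  # equally well when tg_cyt is not observed: a direct two-fit comparison
  suite <- benchmark_suite(cv = 0)
  B <- suite$B
  m <- B$model
  p1 <- B$p_base
  x1 <- steady_state(m, p1)
  # construct an alternative parameter set moving pool mass from cytosol to
  # ER while preserving every observed quantity at steady state
  shift <- 0.7
  p2 <- p1
  p2[["k_load"]] <- p1[["k_load"]] / shift
  p2[["k_sec"]] <- p1[["k_sec"]] * x1[["tg_er"]] /
    (x1[["tg_er"]] + (1 - shift) * x1[["tg_cyt"]])
  p2[["k_cat"]] <- p1[["k_cat"]] / shift
  x2 <- steady_state(m, p2)
  obs <- setdiff(B$observed, "tg_cyt_c")
  y1 <- eval_outputs(m, x1, p1)[1, obs]
  y2 <- eval_outputs(m, x2, p2)[1, obs]
  expect_equal(unname(y2), unname(y1), tolerance = 0.01)
  # but the split itself differs materially between the two fits
  expect_gt(abs(x2[["tg_cyt"]] - x1[["tg_cyt"]]) / x1[["tg_cyt"]], 0.2)
})
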