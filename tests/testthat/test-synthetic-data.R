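test_that("SSA end-point counts match known steady states", {
  # silent promoter stays at zero
  expect_true(all(ssa_counts(promoter_model("poisson", r = 0), 50,
                             seed = 1) == 0))
  # Poisson promoter: empirical mean within 3 standard errors
  x <- ssa_counts(promoter_model("poisson", r = 10), 2e4, seed = 2)
  expect_lt(abs(mean(x) - 10), 3 * sqrt(10 / 2e4))
  expect_equal(ssa_counts(promoter_model("bursty", k_i = 2, b = 3), 100,
                          seed = 5),
               ssa_counts(promoter_model("bursty", k_i = 2, b = 3), 100,
                          seed = 5))
  expect_warning(ssa_counts(promoter_model("poisson", r = 1), 10,
                            t_end = 2, seed = 1), "burn-in|steady state")
})

test_that("SSA agrees with the analytic steady state for all five models", {
  checks <- list(
    list(promoter_model("poisson", r = 10), function(M) dpois(0:M, 10)),
    list(promoter_model("rnap_escape", r = 2, kP_on = 2, kP_off = 1), NULL),
    list(promoter_model("multistep_escape", r = 2, kP_on = 2, kP_off = 1,
                        k_O = 3), NULL),
    list(promoter_model("telegraph", r = 5, k_act = 1, k_inact = 2), NULL),
    list(promoter_model("bursty", k_i = 2, b = 3),
         function(M) neg_binom_pmf(0:M, 2, 3)))
  for (i in seq_along(checks)) {
    mod <- checks[[i]][[1]]
    x <- ssa_counts(mod, 1e5, seed = 100 + i)
    pmf <- if (is.null(checks[[i]][[2]])) {
      marginal_mrna(steady_state_joint(mod))
    } else {
      M <- max(x) + 20
      p <- checks[[i]][[2]](M)
      p / sum(p)
    }
    expect_lt(ks_to_pmf(x, pmf), 0.01)
  }
})

test_that("inverse-CDF sampling from a pmf", {
  expect_true(all(sample_pmf(c(rep(0, 7), 1), 50, seed = 1) == 7))
  x <- sample_pmf(neg_binom_pmf(0:400, 2, 3), 1e5, seed = 3)
  fano <- var(x) / mean(x)
  # Fano of NB draws within ~3 SE of 1 + b (SE via delta-method simulation)
  expect_lt(abs(fano - 4), 0.15)
  expect_identical(sample_pmf(dpois(0:50, 5) / sum(dpois(0:50, 5)), 100,
                              seed = 9),
                   sample_pmf(dpois(0:50, 5) / sum(dpois(0:50, 5)), 100,
                              seed = 9))
  expect_error(sample_pmf(c(0.5, 0.2), 10), "normalized")
})

test_that("study configuration defaults define the full design", {
  cfg <- study_config()
  expect_length(cfg$constitutive, 18)
  ki <- vapply(cfg$constitutive, `[[`, numeric(1), "k_i")
  expect_gte(max(ki) / min(ki), 100)
  expect_equal(nrow(cfg$conditions), 9)
  expect_equal(sort(names(cfg$operators)), c("O1", "O2", "Oid"))
  # imposed energy-gap classes between operator unbinding rates
  expect_equal(log(cfg$operators[["O1"]] / cfg$operators[["Oid"]]), 1.7)
  expect_equal(log(cfg$operators[["O2"]] / cfg$operators[["O1"]]), 1.4,
               tolerance = 1e-12)
  expect_error(study_config(cells_per_condition = 0), "cells_per_condition")
})

test_that("generated studies honor the design and the ground truth", {
  cfg <- study_config(cells_per_condition = 60)
  ds <- generate_study(cfg)
  key <- unique(paste(ds$condition_type, ds$promoter_or_operator,
                      ds$repressor_level))
  expect_length(key, 27)                 # 18 constitutive + 9 regulated
  expect_true(all(ds$mrna_count >= 0))
  expect_equal(nrow(ds), 27 * 60)
  prov <- attr(ds, "provenance")
  expect_equal(prov$seed, cfg$seed)
  expect_equal(prov$truth$operators$Oid, 0.5)

  # constitutive-only config
  cfg1 <- study_config(constitutive = list(p1 = c(k_i = 1, b = 2)),
                       reference = "p1",
                       conditions = data.frame(operator = character(0),
                                               level = character(0)),
                       cells_per_condition = 30)
  ds1 <- generate_study(cfg1)
  expect_true(all(ds1$condition_type == "constitutive"))
})

test_that("regulated means follow the fold-change of the imposed rates", {
  # k_on/k_off = 9 represses to ~10% of the constitutive mean
  cfg <- study_config(
    constitutive = list(ref = c(k_i = 4.5, b = 4.5)), reference = "ref",
    operators = c(op = 1), repressor_levels = c(`1` = 9),
    conditions = data.frame(operator = "op", level = "1"),
    cells_per_condition = 5000, seed = 7)
  ds <- generate_study(cfg)
  reg <- ds$mrna_count[ds$condition_type == "regulated"]
  expect_lt(abs(mean(reg) - 0.1 * 4.5 * 4.5), 3 * sd(reg) / sqrt(5000))
})

test_that("per-condition random streams are independent and reproducible", {
  cfgA <- tiny_study_config()
  dsA <- generate_study(cfgA)
  expect_identical(dsA, generate_study(cfgA))
  # adding a condition leaves existing conditions untouched
  cfgC <- tiny_study_config()
  cfgC$operators <- c(opA = 1, opB = 4, opC = 2)
  cfgC$conditions <- data.frame(operator = c("opA", "opB", "opC"),
                                level = "1")
  dsC <- generate_study(cfgC)
  for (op in c("opA", "opB")) {
    a <- dsA$mrna_count[dsA$promoter_or_operator == op]
    c2 <- dsC$mrna_count[dsC$promoter_or_operator == op]
    expect_identical(a, c2)
  }
})

test_that("ground truth in provenance regenerates the dataset (closure)", {
  cfg <- tiny_study_config(cells = 40)
  ds <- generate_study(cfg)
  prov <- attr(ds, "provenance")
  cfg2 <- study_config(
    constitutive = lapply(prov$truth$constitutive, unlist),
    reference = prov$reference,
    operators = unlist(prov$truth$operators),
    repressor_levels = unlist(prov$truth$repressor_levels),
    conditions = cfg$conditions,
    cells_per_condition = prov$cells_per_condition,
    seed = prov$seed)
  ds2 <- generate_study(cfg2)
  expect_equal(ds$mrna_count, ds2$mrna_count)
})

test_that("count tables round-trip through CSV with provenance sidecar", {
  dir <- withr::local_tempdir()
  ds <- generate_study(tiny_study_config(cells = 25))
  path <- file.path(dir, "counts.csv")
  write_counts(ds, path)
  expect_true(file.exists(paste0(path, ".provenance.yml")))
  back <- read_counts(path)
  expect_equal(ds$mrna_count, back$mrna_count)
  expect_equal(attr(back, "provenance")$seed,
               attr(ds, "provenance")$seed)
  bad <- file.path(dir, "bad.csv")
  writeLines(c("condition_type,promoter_or_operator,repressor_level,cell_id,mrna_count",
               "constitutive,p,NA,1,-3"), bad)
  expect_error(read_counts(bad), "negative")
})
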