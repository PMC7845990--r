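#' Pipeline stage runners
#'
#' These functions tie the package's stages into a file-based, reproducible
#' pipeline: each takes paths plus settings, writes comma-separated result
#' tables into an output directory together with a `run.yml` metadata file
#' (resolved settings and seed, sufficient to re-run the command exactly),
#' and returns its main result invisibly. A thin command-line wrapper over
#' these functions ships in `inst/cli/burstrep.R` with subcommands
#' `simulate`, `fit-constitutive`, `fit-regulated`, `check`, `compare`.
#'
#' @name pipeline
NULL

write_run_meta <- function(out_dir, stage, settings) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(
    c(list(stage = stage,
           package_version = as.character(utils::packageVersion("burstrep")),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      settings),
    file.path(out_dir, "run.yml"))
}

#' @rdname pipeline
#' @param out_dir Output directory (created if needed).
#' @param cfg A [study_config()]; the default study if omitted.
#' @return `run_simulate()`: the generated count data frame, invisibly.
#' @export
run_simulate <- function(out_dir, cfg = study_config()) {
  counts <- generate_study(cfg)
  write_run_meta(out_dir, "simulate",
                 list(seed = cfg$seed,
                      cells_per_condition = cfg$cells_per_condition,
                      n_conditions = length(unique(paste(
                        counts$condition_type, counts$promoter_or_operator,
                        counts$repressor_level)))))
  write_counts(counts, file.path(out_dir, "counts.csv"))
  invisible(counts)
}

#' @rdname pipeline
#' @param counts_path Path to a counts CSV in the [write_counts()] schema.
#' @param promoters Constitutive promoters to fit (default: all present).
#' @param n_steps,n_walkers,seed Sampler settings per promoter.
#' @param override Keep going despite failed convergence gates (the summary
#'   still records R-hat and ESS).
#' @return `run_fit_constitutive()`: the per-promoter summary data frame,
#'   invisibly. Draws are written as `posterior_<promoter>.csv` (log scale,
#'   one column per parameter plus iteration and walker).
#' @export
run_fit_constitutive <- function(counts_path, out_dir, promoters = NULL,
                                 n_steps = 8000, n_walkers = 6, seed = 1,
                                 override = FALSE) {
  dataset <- read_counts(counts_path)
  con <- dataset[dataset$condition_type == "constitutive", , drop = FALSE]
  if (!nrow(con)) stop("no constitutive conditions in ", counts_path)
  if (is.null(promoters)) promoters <- unique(con$promoter_or_operator)
  rows <- list()
  for (pr in promoters) {
    cc <- con$mrna_count[con$promoter_or_operator == pr]
    if (!length(cc)) stop("empty condition: ", pr)
    s <- fit_constitutive(cc, n_steps = n_steps, n_walkers = n_walkers,
                          seed = seed)
    check_converged(s, override)
    write_draws(s, file.path(out_dir, paste0("posterior_", pr, ".csv")),
                make_dir = TRUE)
    sm <- posterior_summary(s, override = TRUE)
    hp_k <- hpd_region(s, "k_i", override = TRUE)
    hp_b <- hpd_region(s, "b", override = TRUE)
    sm$hpd_lower <- c(hp_k[1], hp_b[1])
    sm$hpd_upper <- c(hp_k[2], hp_b[2])
    sm$promoter <- pr
    rows[[pr]] <- sm
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  write_run_meta(out_dir, "fit-constitutive",
                 list(counts = counts_path, seed = seed, n_steps = n_steps,
                      n_walkers = n_walkers, promoters = promoters))
  utils::write.csv(out, file.path(out_dir, "summary.csv"), row.names = FALSE)
  invisible(out)
}

#' @rdname pipeline
#' @param reference,fix_burst,burst See [regulated_model_spec()].
#' @return `run_fit_regulated()`: the fitted `posterior_samples`, invisibly;
#'   writes `posterior_regulated.csv` and `summary.csv`.
#' @export
run_fit_regulated <- function(counts_path, out_dir, reference = "prom09",
                              fix_burst = FALSE, burst = NULL,
                              n_steps = 1200, n_walkers = NULL, seed = 1,
                              override = FALSE) {
  dataset <- read_counts(counts_path)
  s <- fit_regulated(dataset, reference = reference, fix_burst = fix_burst,
                     burst = burst, n_steps = n_steps,
                     n_walkers = n_walkers, seed = seed)
  check_converged(s, override)
  write_draws(s, file.path(out_dir, "posterior_regulated.csv"),
              make_dir = TRUE)
  sm <- posterior_summary(s, override = TRUE)
  utils::write.csv(sm, file.path(out_dir, "summary.csv"), row.names = FALSE)
  write_run_meta(out_dir, "fit-regulated",
                 list(counts = counts_path, seed = seed, n_steps = n_steps,
                      reference = reference, fix_burst = fix_burst))
  invisible(s)
}

#' @rdname pipeline
#' @param posterior_path Path to a draws CSV written by a fit stage.
#' @param model Observation model tag for the predictive check.
#' @param condition For the repressed model, `c(operator, level)`.
#' @param n_rep Posterior predictive replicates.
#' @return `run_check()`: the `ecdf_band`, invisibly; writes `band.csv` and
#'   a `coverage` entry in `run.yml`.
#' @export
run_check <- function(counts_path, posterior_path, out_dir,
                      model = "neg_binom", promoter = NULL,
                      condition = NULL, n_rep = 200, seed = 1,
                      override = FALSE) {
  dataset <- read_counts(counts_path)
  s <- read_draws(posterior_path)
  if (model == "bursty_repressed") {
    stopifnot(length(condition) == 2)
    obs <- dataset$mrna_count[dataset$condition_type == "regulated" &
      dataset$promoter_or_operator == condition[1] &
      dataset$repressor_level == condition[2]]
  } else {
    if (is.null(promoter)) stop("promoter required for constitutive checks")
    obs <- dataset$mrna_count[dataset$condition_type == "constitutive" &
      dataset$promoter_or_operator == promoter]
  }
  if (!length(obs)) stop("no observed cells for the requested condition")
  band <- posterior_predictive_band(s, model, n_cells = length(obs),
                                    observed = obs, condition = condition,
                                    n_rep = n_rep, seed = seed,
                                    override = override)
  write_run_meta(out_dir, "check",
                 list(counts = counts_path, posterior = posterior_path,
                      model = model, seed = seed, n_rep = n_rep,
                      coverage = band_coverage(band)))
  utils::write.csv(as.data.frame(band), file.path(out_dir, "band.csv"),
                   row.names = FALSE)
  invisible(band)
}

#' @rdname pipeline
#' @param reference_energies Optional named list of literature binding-energy
#'   differences (kT) keyed `"<op_a>-<op_b>"`, carried into the comparison
#'   table as user-supplied constants.
#' @param mrna_lifetimes_min mRNA lifetimes (minutes) at which to report
#'   physical dissociation rates.
#' @return `run_compare()`: the comparison data frame, invisibly; written as
#'   `comparison.csv`.
#' @export
run_compare <- function(posterior_path, out_dir,
                        reference_energies = NULL,
                        mrna_lifetimes_min = c(3, 5), seed = 1,
                        override = FALSE) {
  s <- read_draws(posterior_path)
  ops <- sub("^k_off_", "", grep("^k_off_", s$params, value = TRUE))
  if (length(ops) < 2) stop("posterior contains fewer than two operators")
  pairs <- utils::combn(ops, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pp) {
    ed <- energy_difference_posterior(s, pp[1], pp[2], override = override)
    key <- paste0(pp[1], "-", pp[2])
    data.frame(comparison = key, quantity = "delta_eps_kT",
               median = ed$median, lower = ed$lower, upper = ed$upper,
               reference = if (!is.null(reference_energies[[key]]))
                 reference_energies[[key]] else NA_real_)
  })
  x <- draws_matrix(s, natural = TRUE)
  for (op in ops) {
    for (lt in mrna_lifetimes_min) {
      k <- dissociation_rate_to_physical(x[, paste0("k_off_", op)], lt)
      qs <- stats::quantile(k, c(0.025, 0.5, 0.975))
      rows[[length(rows) + 1]] <- data.frame(
        comparison = sprintf("%s@%gmin", op, lt),
        quantity = "k_off_per_s", median = qs[2], lower = qs[1],
        upper = qs[3], reference = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  write_run_meta(out_dir, "compare",
                 list(posterior = posterior_path, seed = seed,
                      lifetimes_min = mrna_lifetimes_min))
  utils::write.csv(out, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  invisible(out)
}

#' Persist and restore posterior draws
#'
#' Draws are stored as a comma-separated table (iteration, walker, one
#' column per parameter, log scale) with a YAML metadata sidecar holding the
#' seed, settings and convergence diagnostics.
#'
#' @param s A `posterior_samples` object.
#' @param path CSV path.
#' @param make_dir Create the parent directory?
#' @return `path` (write) or the reconstructed `posterior_samples` (read).
#' @export
write_draws <- function(s, path, make_dir = FALSE) {
  stopifnot(inherits(s, "posterior_samples"))
  if (make_dir) dir.create(dirname(path), recursive = TRUE,
                           showWarnings = FALSE)
  n <- dim(s$draws)[1]; K <- dim(s$draws)[2]
  flat <- as.data.frame(matrix(s$draws, ncol = length(s$params),
                               dimnames = list(NULL, s$params)))
  out <- cbind(data.frame(iteration = rep(seq_len(n), times = K),
                          walker = rep(seq_len(K), each = n)), flat)
  utils::write.csv(out, path, row.names = FALSE)
  yaml::write_yaml(
    list(params = s$params, seed = s$seed, n_steps = s$n_steps,
         n_walkers = s$n_walkers, warmup = s$warmup,
         accept_rate = s$accept_rate,
         diagnostics = lapply(seq_len(nrow(s$diagnostics)), function(i)
           as.list(s$diagnostics[i, ]))),
    paste0(path, ".meta.yml"))
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  meta_path <- paste0(path, ".meta.yml")
  if (!file.exists(meta_path)) {
    stop("missing metadata sidecar for posterior file: ", meta_path)
  }
  meta <- yaml::read_yaml(meta_path)
  tab <- utils::read.csv(path)
  params <- unlist(meta$params)
  if (!all(c("iteration", "walker", params) %in% names(tab))) {
    stop("posterior file ", path, " does not match its metadata ",
         "(expected columns: ", paste(params, collapse = ", "), ")")
  }
  n <- max(tab$iteration); K <- max(tab$walker)
  if (nrow(tab) != n * K) stop("corrupt posterior file: ", path)
  tab <- tab[order(tab$walker, tab$iteration), ]
  draws <- array(as.matrix(tab[params]), c(n, K, length(params)),
                 dimnames = list(NULL, NULL, params))
  s <- structure(
    list(draws = draws, params = params, seed = meta$seed,
         n_steps = meta$n_steps, n_walkers = K, warmup = meta$warmup,
         accept_rate = meta$accept_rate),
    class = "posterior_samples")
  s$diagnostics <- do.call(rbind, lapply(meta$diagnostics, as.data.frame))
  s
}
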