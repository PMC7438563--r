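#' Experiment plan
#'
#' The full study design: a list of schemes, a replicate count, and a
#' master seed from which every replicate- and scheme-level seed is
#' derived. The `desk` preset keeps every model constant and reduces the
#' replication (10 instead of 100) for single-machine runs.
#'
#' @param schemes named list of [scheme_config()]s (default: the nine of
#'   [standard_schemes()])
#' @param replicates number of replicates
#' @param seed master seed
#' @param sim a [sim_config()]
#' @param scale "full" (100 replicates) or "desk" (10)
#' @return an `experiment_plan`
#' @export
experiment_plan <- function(schemes = standard_schemes(), replicates = NULL,
                            seed = 1, sim = sim_config(),
                            scale = c("desk", "full")) {
  scale <- match.arg(scale)
  if (is.null(replicates)) replicates <- if (scale == "full") 100 else 10
  structure(list(schemes = schemes, replicates = replicates, seed = seed,
                 sim = sim, scale = scale),
            class = "experiment_plan")
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
derive_seed <- function(master, replicate, stage = 0) {
  as.integer((as.numeric(master) * 7919 + replicate * 104729 + stage * 15485863) %%
               2147483647)
}

#' Run the full experiment
#'
#' Runs every scheme on every replicate. All schemes within a replicate
#' share the same base genomes, panels and QTL effects (the replicate
#' base); randomness downstream of selection is scheme-specific. A
#' replicate/scheme combination aborted by a solver failure is logged and
#' excluded from the summaries with its count reported.
#'
#' @param plan an [experiment_plan()]
#' @param out_dir optional directory: per-generation trajectories and
#'   summaries are written as CSV
#' @param verbose print progress
#' @return an `experiment_result`: `runs` (list of lists of `scheme_run`),
#'   `rates` and `gains` summaries, `failures`
#' @export
run_experiment <- function(plan, out_dir = NULL, verbose = FALSE) {
  runs <- list()
  failures <- data.frame(scheme = character(), replicate = integer(),
                         message = character())
  for (r in seq_len(plan$replicates)) {
    base <- replicate_base(derive_seed(plan$seed, r), sim = plan$sim)
    for (si in seq_along(plan$schemes)) {
      cfg <- plan$schemes[[si]]
      if (verbose) message(sprintf("replicate %d: %s", r, cfg$label))
      res <- tryCatch(run_scheme(cfg, base, derive_seed(plan$seed, r, si)),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failures <- rbind(failures, data.frame(scheme = cfg$label,
                                               replicate = r,
                                               message = conditionMessage(res)))
      } else {
        res$replicate <- r
        res$state <- NULL   # drop genotypes: summaries only need trajectories
        runs[[cfg$label]][[r]] <- res
      }
    }
  }
  out <- structure(list(runs = runs,
                        rates = rate_summary(runs),
                        gains = gain_summary(runs),
                        failures = failures, plan = plan),
                   class = "experiment_result")
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

# bind trajectories / per-generation tables over schemes and replicates
bind_runs <- function(runs, what) {
  do.call(rbind, unlist(lapply(names(runs), function(sch) {
    lapply(runs[[sch]], function(run) {
      if (is.null(run)) return(NULL)
      cbind(scheme = sch, replicate = run$replicate, run[[what]])
    })
  }), recursive = FALSE))
}

#' Rates of inbreeding and generation-20 deviation, per scheme and panel
#'
#' For every scheme and panel, estimates the rate of inbreeding from both
#' the heterozygosity and the drift trajectory of each replicate
#' ([delta_f_regression()], reporting the small-rate `-slope` estimate) and
#' the deviation `F_hom - F_drift` in the final generation; means and
#' standard errors are across replicates. A series that reaches `F >= 1`
#' (complete loss of the panel's initial diversity, where `log(1 - F)` is
#' undefined) enters the regression only up to the generation before; if
#' fewer than 3 points remain its rate is dropped from the averages.
#'
#' @param runs the `runs` element of an [run_experiment()] result
#' @return data.frame (scheme, panel, dF_hom, dF_drift, dev_f, with SEs,
#'   n_replicates)
#' @export
rate_summary <- function(runs) {
  traj <- bind_runs(runs, "traj")
  if (is.null(traj)) return(NULL)
  combos <- unique(traj[, c("scheme", "panel")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    d <- traj[traj$scheme == combos$scheme[i] & traj$panel == combos$panel[i], ]
    per_rep <- lapply(split(d, d$replicate), function(dr) {
      dr <- dr[order(dr$generation), ]
      last <- dr[nrow(dr), ]
      # log(1 - F) is only defined below complete diversity loss: the
      # regression uses the series up to the first generation with F >= 1
      reg <- function(f, t) {
        keep <- if (any(f >= 1)) seq_len(which(f >= 1)[1] - 1L) else seq_along(f)
        if (length(keep) < 3) return(NA_real_)
        delta_f_regression(f[keep], t[keep])$dF_approx
      }
      c(dF_hom = reg(dr$F_hom, dr$generation),
        dF_drift = reg(dr$F_drift, dr$generation),
        dev_f = last$F_hom - last$F_drift)
    })
    m <- do.call(rbind, per_rep)
    mn <- function(x) mean(x, na.rm = TRUE)
    se <- function(x) {
      x <- x[!is.na(x)]
      sd(x) / sqrt(length(x))
    }
    data.frame(scheme = combos$scheme[i], panel = combos$panel[i],
               dF_hom = mn(m[, "dF_hom"]), dF_hom_se = se(m[, "dF_hom"]),
               dF_drift = mn(m[, "dF_drift"]), dF_drift_se = se(m[, "dF_drift"]),
               dev_f = mn(m[, "dev_f"]), dev_f_se = se(m[, "dev_f"]),
               n_replicates = nrow(m))
  })
  do.call(rbind, out)
}

#' Genetic gain and final inbreeding, per scheme
#'
#' Gain after the final generation in base genetic SD units (mean over
#' replicates with its SE) together with the final-generation `F_hom` and
#' `F_drift` on the neutral Panel N.
#'
#' @param runs the `runs` element of an [run_experiment()] result
#' @return data.frame (scheme, gain, gain_se, F_hom_N, F_drift_N,
#'   n_replicates)
#' @export
gain_summary <- function(runs) {
  pergen <- bind_runs(runs, "pergen")
  traj <- bind_runs(runs, "traj")
  if (is.null(pergen)) return(NULL)
  out <- lapply(unique(pergen$scheme), function(sch) {
    d <- pergen[pergen$scheme == sch, ]
    gain <- vapply(split(d, d$replicate), function(dr) {
      dr$gain[which.max(dr$generation)]
    }, numeric(1))
    tN <- traj[traj$scheme == sch & traj$panel == "N", ]
    fin <- tN[tN$generation == max(tN$generation), ]
    se <- function(x) sd(x) / sqrt(length(x))
    data.frame(scheme = sch, gain = mean(gain), gain_se = se(gain),
               F_hom_N = mean(fin$F_hom), F_drift_N = mean(fin$F_drift),
               n_replicates = length(gain))
  })
  do.call(rbind, out)
}

#' Paired comparison of two schemes at matched inbreeding
#'
#' For every replicate, the comparison scheme's gain-versus-inbreeding
#' curve (inbreeding = mean of `F_hom` and `F_drift` on Panel N) is
#' linearly interpolated at the reference scheme's final-generation
#' inbreeding, and a win is counted when the reference gain strictly
#' exceeds the interpolated gain. Interpolation outside the comparison
#' curve's range clamps to its end values.
#'
#' @param runs_ref,runs_cmp lists of `scheme_run` objects (same replicate
#'   indexing)
#' @return list: `wins`, `n`, and a per-replicate data.frame
#' @export
paired_comparison <- function(runs_ref, runs_cmp) {
  stopifnot(length(runs_ref) == length(runs_cmp))
  detail <- lapply(seq_along(runs_ref), function(r) {
    a <- runs_ref[[r]]; b <- runs_cmp[[r]]
    if (is.null(a) || is.null(b)) return(NULL)
    curve <- function(run) {
      tN <- run$traj[run$traj$panel == "N", ]
      tN <- tN[order(tN$generation), ]
      data.frame(generation = tN$generation,
                 f = (tN$F_hom + tN$F_drift) / 2,
                 gain = run$pergen$gain[match(tN$generation,
                                              run$pergen$generation)])
    }
    ca <- curve(a); cb <- curve(b)
    f_ref <- ca$f[nrow(ca)]
    g_ref <- ca$gain[nrow(ca)]
    g_cmp <- stats::approx(cb$f, cb$gain, xout = f_ref, rule = 2,
                           ties = "ordered")$y
    data.frame(replicate = r, f_ref = f_ref, gain_ref = g_ref,
               gain_cmp_interp = g_cmp, win = g_ref > g_cmp)
  })
  detail <- do.call(rbind, detail)
  list(wins = sum(detail$win), n = nrow(detail), detail = detail)
}

#' Write experiment outputs as CSV
#'
#' Persists raw per-generation trajectories (`traj.csv`, `pergen.csv`) and
#' the two summary tables; [summarize_experiment()] rebuilds the summaries
#' from the raw files.
#'
#' @param result an [run_experiment()] result
#' @param out_dir output directory (created if needed)
#' @return `out_dir`, invisibly
#' @export
write_experiment <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(bind_runs(result$runs, "traj"),
            file.path(out_dir, "traj.csv"), row.names = FALSE)
  write.csv(bind_runs(result$runs, "pergen"),
            file.path(out_dir, "pergen.csv"), row.names = FALSE)
  write.csv(result$rates, file.path(out_dir, "rates_summary.csv"),
            row.names = FALSE)
  write.csv(result$gains, file.path(out_dir, "gain_summary.csv"),
            row.names = FALSE)
  if (nrow(result$failures)) {
    write.csv(result$failures, file.path(out_dir, "failures.csv"),
              row.names = FALSE)
  }
  invisible(out_dir)
}

#' Rebuild per-replicate runs from persisted trajectories
#'
#' Reads `traj.csv` / `pergen.csv` written by [write_experiment()] back
#' into the per-scheme, per-replicate list structure that the summary and
#' comparison functions consume.
#'
#' @param in_dir directory written by [write_experiment()]
#' @return named list (scheme) of lists (replicate) of trajectory records
#' @export
read_experiment <- function(in_dir) {
  traj <- read.csv(file.path(in_dir, "traj.csv"))
  pergen <- read.csv(file.path(in_dir, "pergen.csv"))
  runs <- list()
  for (sch in unique(traj$scheme)) {
    for (r in unique(traj$replicate[traj$scheme == sch])) {
      runs[[sch]][[r]] <- list(
        replicate = r,
        traj = traj[traj$scheme == sch & traj$replicate == r,
                    setdiff(names(traj), c("scheme", "replicate"))],
        pergen = pergen[pergen$scheme == sch & pergen$replicate == r,
                        setdiff(names(pergen), c("scheme", "replicate"))])
    }
  }
  runs
}

#' Rebuild summaries from persisted trajectories
#'
#' @param in_dir directory written by [write_experiment()]
#' @return list with `rates` and `gains` summaries
#' @export
summarize_experiment <- function(in_dir) {
  runs <- read_experiment(in_dir)
  list(rates = rate_summary(runs), gains = gain_summary(runs))
}
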