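# Sweep reproductions and CSV plumbing. Every emitted CSV carries header
# comment lines (prefixed '#') recording the package version, the
# configuration and the seed, so a file can be regenerated byte-identically
# from its own header.

log_level_rank <- c(DEBUG = 1, INFO = 2, WARN = 3, ERROR = 4)

#' @noRd
collnav_log <- function(level, fmt, ...) {
  threshold <- getOption("collnav.log_level", "INFO")
  if (log_level_rank[[level]] >= log_level_rank[[threshold]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  invisible(NULL)
}

#' Write a sweep table as annotated CSV
#'
#' Writes `df` to `path` preceded by `#`-prefixed header lines carrying the
#' package version, the flattened `config` and the `seed`, so that the file
#' documents how to regenerate itself. [read_collnav_csv()] skips the
#' header.
#'
#' @param df A data frame.
#' @param path Output file path.
#' @param config Named list recorded in the header.
#' @param seed Seed recorded in the header (may be `NULL`).
#' @return `path`, invisibly.
#' @export
write_collnav_csv <- function(df, path, config = list(), seed = NULL) {
  cfg <- paste(sprintf("%s=%s", names(config),
                       vapply(config, function(x) paste(format(x), collapse = " "),
                              character(1))),
               collapse = ", ")
  header <- c(
    sprintf("# collnav %s", as.character(utils::packageVersion("collnav"))),
    sprintf("# config: %s", cfg),
    sprintf("# seed: %s", if (is.null(seed)) "NA" else format(seed)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a collnav-annotated CSV
#'
#' @param path File written by [write_collnav_csv()].
#' @return The data frame (header comments dropped).
#' @export
read_collnav_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Target error versus target weighting, with optimal and ESS summaries
#'
#' Evaluates the homogeneous equilibrium target error over a grid of target
#' weightings for each interaction-noise value, and appends per-noise
#' summary rows with the collectively optimal and ESS weightings and their
#' errors. Per-point solver failures are recorded as `NA` with a warning
#' log line rather than aborting the sweep.
#'
#' @param n Group size.
#' @param gamma_list Interaction-noise values to sweep.
#' @param w_grid Target-weighting grid (strictly positive values).
#' @return A data frame with columns `kind` (`"curve"` or `"summary"`),
#'   `gamma`, `w`, `sigma`, `w_star`, `sigma_star`, `w_ess`, `sigma_ess`
#'   (summary columns `NA` on curve rows and vice versa).
#' @examples
#' head(run_fig1_sweep(10, c(0.5, 1), w_grid = seq(0.1, 1, 0.1)))
#' @export
run_fig1_sweep <- function(n = 10, gamma_list = c(0.25, 0.5, 1, 2, 4),
                           w_grid = seq(0.01, 1, by = 0.01)) {
  stopifnot(all(w_grid > 0), all(w_grid <= 1), all(gamma_list >= 0))
  rows <- list()
  for (g in gamma_list) {
    sig <- vapply(w_grid, function(w) {
      tryCatch(equilibrium_sigma(w, n, g)$sigma,
               error = function(e) {
                 collnav_log("WARN", "fig1 point failed (w=%g, gamma=%g): %s",
                             w, g, conditionMessage(e))
                 NA_real_
               })
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "curve", gamma = g, w = w_grid, sigma = sig,
      w_star = NA_real_, sigma_star = NA_real_,
      w_ess = NA_real_, sigma_ess = NA_real_)
    opt <- tryCatch(collective_optimal_w(n, g), error = function(e) NULL)
    ess <- tryCatch(ess_w(n, g), error = function(e) NULL)
    if (is.null(opt) || is.null(ess))
      collnav_log("WARN", "fig1 summary failed for gamma=%g", g)
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "summary", gamma = g, w = NA_real_, sigma = NA_real_,
      w_star = if (is.null(opt)) NA_real_ else opt$w_star,
      sigma_star = if (is.null(opt)) NA_real_ else opt$sigma,
      w_ess = if (is.null(ess)) NA_real_ else ess$w_ess,
      sigma_ess = if (is.null(ess)) NA_real_ else ess$sigma)
  }
  do.call(rbind, rows)
}

#' Optimal and ESS strategies of an expert/naive group across noise levels
#'
#' For each naive-noise level in `epsilon_grid`, computes both the
#' collectively optimal strategy ([collective_optimum()]) and the
#' evolutionarily stable strategy ([mixed_ess()]) of a group with `nA`
#' experts and `nB` naive agents.
#'
#' @param nA,nB Type counts (defaults: one expert, nine naive agents).
#' @param gamma Interaction noise.
#' @param epsilon_grid Naive-agent noise levels (`>= 1`).
#' @param seed Optional seed (random restarts of the optimiser).
#' @return A data frame with columns `epsilon`, `mode` (`"optimal"` or
#'   `"ess"`), `wA`, `wB`, `alphaA`, `alphaB`, `sigmaA`, `sigmaB`,
#'   `collective_error`; failed points carry `NA`.
#' @examples
#' \donttest{run_fig2_sweep(epsilon_grid = c(1, 4))}
#' @export
run_fig2_sweep <- function(nA = 1, nB = 9, gamma = 0.5,
                           epsilon_grid = c(1, 2, 4, 8, 16), seed = NULL) {
  stopifnot(all(epsilon_grid >= 1))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (e in epsilon_grid) {
    for (mode in c("optimal", "ess")) {
      fit <- tryCatch({
        if (mode == "optimal") {
          o <- collective_optimum(nA, nB, e, gamma)
          list(p = o$params, eq = o$equilibrium, ce = o$collective_error)
        } else {
          o <- mixed_ess(nA, nB, e, gamma)
          list(p = o$params, eq = o$equilibrium,
               ce = collective_error(o$equilibrium, nA, nB))
        }
      }, error = function(err) {
        collnav_log("WARN", "fig2 point failed (epsilon=%g, %s): %s",
                    e, mode, conditionMessage(err))
        NULL
      })
      rows[[length(rows) + 1L]] <- if (is.null(fit)) {
        data.frame(epsilon = e, mode = mode, wA = NA_real_, wB = NA_real_,
                   alphaA = NA_real_, alphaB = NA_real_, sigmaA = NA_real_,
                   sigmaB = NA_real_, collective_error = NA_real_)
      } else {
        data.frame(epsilon = e, mode = mode,
                   wA = fit$p$wA, wB = fit$p$wB,
                   alphaA = fit$p$alphaA, alphaB = fit$p$alphaB,
                   sigmaA = fit$eq$sigmaA, sigmaB = fit$eq$sigmaB,
                   collective_error = fit$ce)
      }
    }
  }
  do.call(rbind, rows)
}

#' Bifurcation scan across group sizes
#'
#' Delegates to [bifurcation_scan()] for each group size in `n_list` and
#' aggregates the per-run outcomes and per-size critical cost exponents.
#'
#' @param n_list Group sizes to scan.
#' @param k_grid Cost-exponent grid, passed through.
#' @param replicates Runs per grid value.
#' @param steps Steps per run; default `50000 * n` per group size.
#' @param seed Optional integer seed set once before the whole scan.
#' @return A list with `results` (per run and agent, with an `n` column) and
#'   `critical` (data frame `n`, `critical_k`).
#' @export
run_fig4_scan <- function(n_list = 2, k_grid = seq(0.5, 3, by = 0.25),
                          replicates = 10, steps = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  all_res <- list(); crit <- list()
  for (n in n_list) {
    sc <- bifurcation_scan(k_grid, n = n, replicates = replicates,
                           steps = if (is.null(steps)) 50000 * n else steps)
    sc$results$n <- n
    all_res[[length(all_res) + 1L]] <- sc$results
    crit[[length(crit) + 1L]] <- data.frame(n = n, critical_k = sc$critical_k)
  }
  list(results = do.call(rbind, all_res), critical = do.call(rbind, crit))
}
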