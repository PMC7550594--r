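#' Sweep optimal groups over access ratios and fitness modes
#'
#' For every combination of fitness mode, access ratio `H`, and seed, runs
#' one full genetic optimization, summarizes the averaged optimal genome
#' (network hierarchy at three edge thresholds, out-degree spread, trait
#' means and spreads), and re-evaluates it on fresh runs to obtain its
#' achieved accuracy and consensus performance. Each record logs the seed it
#' was produced from and is reproducible from it.
#'
#' When `out_dir` is given, records are appended to
#' `file.path(out_dir, "records.csv")` as they complete and per-record
#' genomes are written as JSON; re-running the same sweep skips completed
#' (mode, H, seed) triples, so an interrupted sweep resumes where it
#' stopped. Individual optimization failures are logged as `status =
#' "failed"` records, not raised.
#'
#' @param modes Character vector of fitness modes.
#' @param H_values Numeric vector of access ratios (the reference grid is
#'   `seq(0, 1, by = 0.1)`).
#' @param run_config Base [run_config()]; its `fitness_mode` and
#'   `access_ratio` are overridden per record.
#' @param ga_config A [ga_config()].
#' @param n_seeds Number of independent optimizations per (mode, H) cell.
#' @param eval_replicates Fresh runs used to score the averaged optimal
#'   genome.
#' @param out_dir Optional directory for incremental records and genomes.
#' @param master_seed Integer; all per-record seeds are derived from it.
#' @return A tibble of sweep records (one row per (mode, H, seed)).
#' @export
sweep_optimal_groups <- function(modes = c("accuracy", "consensus", "both"),
                                 H_values = seq(0, 1, by = 0.1),
                                 run_config = profile_config("desk")$run,
                                 ga_config = profile_config("desk")$ga,
                                 n_seeds = 5L,
                                 eval_replicates = 50L,
                                 out_dir = NULL,
                                 master_seed = 1L) {
  grid <- tidyr::expand_grid(
    fitness_mode = modes,
    H = H_values,
    seed_index = seq_len(n_seeds)
  )
  set.seed(master_seed)
  grid$seed <- derive_seeds(nrow(grid))
  records_path <- if (!is.null(out_dir)) file.path(out_dir, "records.csv")
  done <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (file.exists(records_path)) {
      done <- as_tibble(read.csv(records_path, stringsAsFactors = FALSE))
    }
  }
  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    if (!is.null(done) && any(
      done$fitness_mode == g$fitness_mode &
        abs(done$H - g$H) < 1e-12 &
        done$seed_index == g$seed_index
    )) {
      rows[[r]] <- done[
        done$fitness_mode == g$fitness_mode &
          abs(done$H - g$H) < 1e-12 &
          done$seed_index == g$seed_index, ,
        drop = FALSE
      ][1L, ]
      next
    }
    cfg <- run_config
    cfg$fitness_mode <- g$fitness_mode
    cfg$access_ratio <- g$H
    rec <- tryCatch(
      sweep_record(cfg, ga_config, g, eval_replicates, out_dir),
      error = function(e) {
        warn(sprintf(
          "optimization failed for mode=%s H=%.2f seed=%d: %s",
          g$fitness_mode, g$H, g$seed, conditionMessage(e)
        ))
        dplyr::mutate(g,
          status = "failed",
          hierarchy = NA_real_, hierarchy_01 = NA_real_,
          hierarchy_05 = NA_real_, out_degree_sd = NA_real_,
          mean_p_comm = NA_real_, sd_p_comm = NA_real_,
          mean_p_obs = NA_real_, sd_p_obs = NA_real_,
          mean_s = NA_real_, sd_s = NA_real_,
          alpha_acc = NA_real_, alpha_cons = NA_real_,
          best_fitness = NA_real_
        )
      }
    )
    rows[[r]] <- rec
    if (!is.null(out_dir)) {
      write.csv(dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))]),
        records_path,
        row.names = FALSE
      )
    }
  }
  dplyr::bind_rows(rows)
}

sweep_record <- function(cfg, ga_config, g, eval_replicates, out_dir) {
  res <- optimize_group(cfg, ga_config, seed = g$seed)
  genome <- res$optimal_genome
  w <- materialize_network(genome)
  runs <- simulate_runs(genome, cfg, eval_replicates)
  if (!is.null(out_dir)) {
    write_genome(genome, file.path(out_dir, sprintf(
      "genome_%s_H%03d_s%02d.json",
      cfg$fitness_mode, round(cfg$access_ratio * 100), g$seed_index
    )))
  }
  dplyr::mutate(g,
    status = "ok",
    hierarchy = network_hierarchy(w, 1e-3),
    hierarchy_01 = network_hierarchy(w, 1e-2),
    hierarchy_05 = network_hierarchy(w, 0.05),
    out_degree_sd = pop_sd(rowSums(w)),
    mean_p_comm = mean(genome$traits$p_comm),
    sd_p_comm = pop_sd(genome$traits$p_comm),
    mean_p_obs = mean(genome$traits$p_obs),
    sd_p_obs = pop_sd(genome$traits$p_obs),
    mean_s = mean(genome$traits$s),
    sd_s = pop_sd(genome$traits$s),
    alpha_acc = mean(runs$alpha_acc),
    alpha_cons = mean(runs$alpha_cons),
    best_fitness = res$history$best_fitness[nrow(res$history)]
  )
}

sweep_metric_cols <- c(
  "hierarchy", "hierarchy_01", "hierarchy_05", "out_degree_sd",
  "mean_p_comm", "mean_p_obs", "mean_s", "alpha_acc", "alpha_cons"
)

#' Monotonic-trend report for a sweep table
#'
#' For each fitness mode and each summary metric, computes the Spearman rank
#' correlation against `H` together with a label-shuffling permutation
#' p-value (two-sided, `(1 + #more extreme) / (n_permutations + 1)`). A
#' metric that is constant across records is reported with correlation 0
#' and p-value 1. A mode observed at fewer than two distinct `H` values is
#' marked underpowered and its correlations are not computed.
#'
#' @param records A sweep tibble from [sweep_optimal_groups()].
#' @param n_permutations Number of label shuffles.
#' @param seed Seed for the permutation draws (the report is deterministic
#'   given the table and this seed).
#' @param out_dir Optional directory; writes `trends.csv` and `trends.md`.
#' @return A list of class `trend_report`: `stats` (tibble with `mode`,
#'   `metric`, `spearman_rho`, `p_value`, `n`, `underpowered`) and
#'   `markdown` (character).
#' @export
trend_report <- function(records, n_permutations = 10000L, seed = 1L,
                         out_dir = NULL) {
  set.seed(seed)
  ok <- records[records$status == "ok", , drop = FALSE]
  stats_rows <- list()
  for (mode in unique(ok$fitness_mode)) {
    sub <- ok[ok$fitness_mode == mode, , drop = FALSE]
    underpowered <- length(unique(sub$H)) < 2L
    for (metric in intersect(sweep_metric_cols, names(sub))) {
      y <- sub[[metric]]
      h <- sub$H
      keep <- is.finite(y) & is.finite(h)
      y <- y[keep]
      h <- h[keep]
      if (underpowered || length(y) < 3L) {
        stats_rows[[length(stats_rows) + 1L]] <- tibble(
          mode = mode, metric = metric, spearman_rho = NA_real_,
          p_value = NA_real_, n = length(y), underpowered = TRUE
        )
        next
      }
      res <- spearman_permutation(h, y, n_permutations)
      stats_rows[[length(stats_rows) + 1L]] <- tibble(
        mode = mode, metric = metric, spearman_rho = res$rho,
        p_value = res$p, n = length(y), underpowered = FALSE
      )
    }
  }
  stats <- dplyr::bind_rows(stats_rows)
  md <- c(
    "# Trend report", "",
    "| mode | metric | Spearman rho | p (permutation) | n |",
    "|---|---|---|---|---|",
    sprintf(
      "| %s | %s | %s | %s | %d |",
      stats$mode, stats$metric,
      ifelse(is.na(stats$spearman_rho), "underpowered",
        sprintf("%.3f", stats$spearman_rho)
      ),
      ifelse(is.na(stats$p_value), "-", sprintf("%.4g", stats$p_value)),
      stats$n
    )
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(stats, file.path(out_dir, "trends.csv"), row.names = FALSE)
    writeLines(md, file.path(out_dir, "trends.md"))
  }
  structure(list(stats = stats, markdown = paste(md, collapse = "\n")),
    class = "trend_report"
  )
}

spearman_permutation <- function(h, y, n_permutations) {
  if (pop_sd(y) == 0 || pop_sd(h) == 0) {
    return(list(rho = 0, p = 1))
  }
  rho <- cor(h, y, method = "spearman")
  ry <- rank(y)
  rh <- rank(h)
  extreme <- 0L
  for (p in seq_len(n_permutations)) {
    rho_p <- cor(rh, ry[fy_shuffle(length(ry))], method = "pearson")
    if (abs(rho_p) >= abs(rho) - 1e-12) extreme <- extreme + 1L
  }
  list(rho = rho, p = (1L + extreme) / (n_permutations + 1L))
}

#' @export
print.trend_report <- function(x, ...) {
  cat(x$markdown, "\n")
  invisible(x)
}

#' Communication collapse under rising communication cost
#'
#' A reduced-scale, qualitative demonstration: optimizes accuracy-mode
#' groups at a fixed access ratio while the cost of communication is set to
#' a series of ratios of the cost of observation, and reports how much
#' materialized communication survives. When communication costs more than
#' roughly 40% of observation, maintaining the network stops paying off and
#' it falls apart. This demo is qualitative; it is not an acceptance
#' surface.
#'
#' @param ratios Ratios `cost_comm / cost_obs` to scan.
#' @param run_config Base [run_config()] (mode forced to accuracy).
#' @param ga_config A [ga_config()].
#' @param seed Master seed.
#' @return A tibble with one row per ratio: total materialized edge weight,
#'   mean communication activity, and best fitness.
#' @export
cost_ratio_demo <- function(ratios = c(0.1, 0.4, 0.6),
                            run_config = profile_config("desk")$run,
                            ga_config = profile_config("desk")$ga,
                            seed = 1L) {
  set.seed(seed)
  seeds <- derive_seeds(length(ratios))
  purrr::map2_dfr(ratios, seeds, function(ratio, s) {
    cfg <- run_config
    cfg$fitness_mode <- "accuracy"
    cfg$cost_comm <- ratio * cfg$cost_obs
    res <- optimize_group(cfg, ga_config, seed = s)
    w <- materialize_network(res$optimal_genome)
    tibble(
      ratio = ratio,
      cost_comm = cfg$cost_comm,
      total_edge_weight = sum(w),
      mean_p_comm = mean(res$optimal_genome$traits$p_comm),
      best_fitness = res$history$best_fitness[nrow(res$history)]
    )
  })
}
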