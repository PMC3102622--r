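#' l1-based accuracy of a recombination-count estimate
#'
#' Scores an estimated recombination-count distribution against the true
#' simulated count as `2 - sum_i |x_i - a_i|`, where `x` is the estimated
#' pmf and `a` the point mass at the true count. The score ranges from 0
#' (no mass on the truth) to 2 (all mass on the truth) and, for a
#' normalized pmf, equals `2 * x[true_count]`.
#'
#' @param estimated A [recombination_distribution()] result, or a bare
#'   numeric pmf over counts `0, 1, ...`.
#' @param true_count Non-negative integer, the simulated number of
#'   recombinations in the interval.
#' @return A value in `[0, 2]`.
#' @examples
#' recomb_accuracy(c(0.5, 0.5), true_count = 0)  # 1
#' @export
recomb_accuracy <- function(estimated, true_count) {
  pmf <- if (inherits(estimated, "recomb_distribution")) estimated$pmf else estimated
  pmf <- as.numeric(pmf)
  if (abs(sum(pmf) - 1) > 1e-9) {
    stop("estimated pmf must be normalized (sums to 1)")
  }
  if (true_count < 0) stop("true_count must be a non-negative integer")
  width <- max(length(pmf), true_count + 1)
  x <- c(pmf, numeric(width - length(pmf)))
  a <- numeric(width)
  a[true_count + 1] <- 1
  2 - sum(abs(x - a))
}

#' Untype founders one at a time
#'
#' The masking schedule used to study how estimate accuracy degrades as
#' founders go untyped: the empty set, then the first founder (in
#' pedigree row order), then the first two, and so on up to all founders.
#'
#' @param ped A [pedigree()].
#' @return A list of character vectors, each a set of untyped individuals.
#' @export
founder_untyped_schedule <- function(ped) {
  fo <- founders(ped)
  c(list(character(0)), lapply(seq_along(fo), function(m) fo[seq_len(m)]))
}

#' Haplotype-versus-genotype accuracy experiment
#'
#' Replicates the simulation comparison of recombination estimates from
#' haplotype and genotype data on one pedigree. For each replicate, a
#' gene-dropping simulation produces fully typed data; for each untyped
#' set in the schedule, the data are masked, the inheritance HMM is run
#' under both data kinds, the posterior recombination-count distribution
#' at the central interval is extracted, and the [recomb_accuracy()]
#' against the simulated truth is recorded.
#'
#' @param ped A [pedigree()].
#' @param untyped_schedule List of character vectors of untyped
#'   individuals (default: [founder_untyped_schedule()]).
#' @param replicates Number of simulation replicates.
#' @param seed Integer master seed.
#' @param max_states Cap forwarded to [forward_backward()].
#' @param ... Further arguments (e.g. `theta_tight`, `loci`) passed to
#'   [default_scenario()].
#' @return An object of class `"accuracy_experiment"`: a list with
#'   `records` (a data frame with one row per replicate x condition x
#'   data kind: `replicate`, `condition`, `n_untyped`, `data_kind`,
#'   `interval`, `true_count`, `accuracy`) and `summary` (per-condition,
#'   per-kind mean accuracy with standard errors).
#' @export
run_accuracy_experiment <- function(ped, untyped_schedule = NULL,
                                    replicates = 200, seed = 1,
                                    max_states = 2^20, ...) {
  if (is.null(untyped_schedule)) untyped_schedule <- founder_untyped_schedule(ped)
  scenario <- default_scenario(ped, seed = seed, ...)
  central <- scenario$central_interval
  n_cond <- length(untyped_schedule)
  rows <- vector("list", replicates * n_cond * 2)
  ri <- 0L
  for (rep_i in seq_len(replicates)) {
    sim <- sim_gene_drop(scenario, replicate = rep_i)
    truth <- sim$true_recomb[central]
    for (ci in seq_len(n_cond)) {
      masked <- mask_data(sim, untyped_schedule[[ci]])
      for (kind in c("haplotype", "genotype")) {
        data <- if (kind == "haplotype") masked$haplotypes else masked$genotypes
        fb <- forward_backward(ped, scenario$map, data, kind, max_states)
        dist <- recombination_distribution(fb, central)
        acc <- recomb_accuracy(dist, truth)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          replicate = rep_i, condition = ci,
          n_untyped = length(untyped_schedule[[ci]]),
          data_kind = kind, interval = central,
          true_count = truth, accuracy = acc,
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, rows)
  agg <- stats::aggregate(accuracy ~ condition + n_untyped + data_kind,
                          data = records,
                          FUN = function(x) c(mean = mean(x),
                                              se = stats::sd(x) / sqrt(length(x)),
                                              n = length(x)))
  summary_df <- data.frame(
    condition = agg$condition, n_untyped = agg$n_untyped,
    data_kind = agg$data_kind,
    mean_accuracy = agg$accuracy[, "mean"],
    se = agg$accuracy[, "se"],
    n_replicates = agg$accuracy[, "n"])
  summary_df <- summary_df[order(summary_df$condition, summary_df$data_kind), ]
  rownames(summary_df) <- NULL
  structure(list(records = records, summary = summary_df,
                 scenario = scenario, untyped_schedule = untyped_schedule),
            class = "accuracy_experiment")
}

#' @export
print.accuracy_experiment <- function(x, ...) {
  cat("Haplotype vs genotype recombination-estimate accuracy\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
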