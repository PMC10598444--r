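## Simulation pipeline: how does the number of modules of a random
## nested-canalizing network relate to its dynamical complexity and its
## phenotypical robustness? For each module count m, random modular networks
## are generated, a fixed set of random initial states is followed to
## attractors (lower bound on the attractor count), and the same initial
## states, each with one random bit flip, estimate the phenotypical
## robustness. Mean robustness as a function of attractor count is then
## summarised by the decay curve y = alpha + (1 - alpha) * exp(-k (x - 1)),
## which passes through (1, 1) by construction.

#' Run the modularity / robustness / complexity experiment
#'
#' @param N Network size (number of variables).
#' @param module_counts Integer vector of module counts `m` to compare;
#'   every `m` must divide `N` with `N/m > in_degree`.
#' @param in_degree Fixed in-degree of every node.
#' @param networks_per_condition Number of random networks per `m`.
#' @param n_samples Random initial states per network, reused for the
#'   robustness estimate.
#' @param seed Integer seed; the full experiment is reproducible from it.
#' @return A tibble with one row per network: `m`, `replicate`,
#'   `net_seed`, `n_attractors_found`, `r_estimate`.
#' @export
run_experiment <- function(N = 12L, module_counts = 1:3, in_degree = 3L,
                           networks_per_condition = 100L, n_samples = 500L,
                           seed = 1L) {
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(networks_per_condition),
                      m = module_counts)
  net_seeds <- sample.int(.Machine$integer.max, nrow(grid))
  rows <- purrr::pmap(
    list(grid$m, grid$replicate, net_seeds),
    function(m, rep, net_seed) {
      net <- generate_modular_network(N, m, in_degree, seed = net_seed)
      aset <- sample_attractors(net, n_samples)
      rob <- sampled_robustness(net, n_samples, aset = aset)
      tibble::tibble(m = m, replicate = rep, net_seed = net_seed,
                     n_attractors_found = length(aset$attractors),
                     r_estimate = rob$r_estimate)
    })
  dplyr::bind_rows(rows)
}

#' Summarise experiment records
#'
#' @param records Tibble from [run_experiment()].
#' @return A list of tibbles: `by_m` (per module count: mean and median
#'   attractor count, mean robustness), `ecdf` (cumulative fraction of
#'   networks with at most `n_attractors_found` attractors, stratified by
#'   `m`) and `by_bin` (mean robustness per `(m, n_attractors_found)` bin
#'   with bin sizes).
#' @export
summarize_experiment <- function(records) {
  if (!nrow(records)) {
    empty <- tibble::tibble()
    return(list(by_m = empty, ecdf = empty, by_bin = empty))
  }
  by_m <- records |>
    dplyr::group_by(m) |>
    dplyr::summarise(
      n_networks = dplyr::n(),
      mean_attractors = mean(n_attractors_found),
      median_attractors = stats::median(n_attractors_found),
      mean_robustness = mean(r_estimate),
      .groups = "drop")
  ecdf_tbl <- records |>
    dplyr::count(m, n_attractors_found) |>
    dplyr::group_by(m) |>
    dplyr::arrange(n_attractors_found, .by_group = TRUE) |>
    dplyr::mutate(cum_fraction = cumsum(n) / sum(n)) |>
    dplyr::ungroup()
  by_bin <- records |>
    dplyr::group_by(m, n_attractors_found) |>
    dplyr::summarise(n_networks = dplyr::n(),
                     mean_robustness = mean(r_estimate),
                     .groups = "drop")
  list(by_m = by_m, ecdf = ecdf_tbl, by_bin = by_bin)
}

#' Fit the robustness decay curve
#'
#' Mean robustness `y` per attractor count `x` is summarised by the
#' two-parameter decay `y = alpha + (1 - alpha) * exp(-k * (x - 1))`:
#' `alpha` is the asymptotic robustness retained at high dynamical
#' complexity and `k` the decay rate; the curve passes through `(1, 1)` by
#' construction, matching `r = 1` for single-attractor networks.
#'
#' @param records Tibble with columns `n_attractors_found` and `r_estimate`
#'   (one row per network), or precomputed means with columns `x` and `y`.
#' @param x_range Attractor counts included in the fit (default `1:19`).
#' @param min_bin Attractor-count bins with fewer networks than this are
#'   excluded (sparse bins destabilise the least-squares fit); ignored for
#'   precomputed means.
#' @return An object of class `bn_decay_fit`: list with `alpha`, `k`,
#'   `means` (the fitted-to tibble with `x`, `y`, `n`) and the underlying
#'   `nls` fit object.
#' @export
fit_robustness_decay <- function(records, x_range = 1:19, min_bin = 5L) {
  if (all(c("x", "y") %in% names(records))) {
    means <- tibble::tibble(
      x = records$x, y = records$y,
      n = if ("n" %in% names(records)) records$n else rep(1L, nrow(records)))
  } else {
    means <- records |>
      dplyr::group_by(x = n_attractors_found) |>
      dplyr::summarise(y = mean(r_estimate), n = dplyr::n(),
                       .groups = "drop") |>
      dplyr::filter(n >= min_bin)
  }
  means <- means[means$x %in% x_range, , drop = FALSE]
  if (length(unique(means$x)) < 2L) {
    stop("need at least two distinct attractor-count bins to fit the decay")
  }
  fit <- minpack.lm::nlsLM(
    y ~ alpha + (1 - alpha) * exp(-k * (x - 1)),
    data = means,
    start = list(alpha = max(0, min(means$y)), k = 0.5),
    lower = c(alpha = 0, k = 0),
    upper = c(alpha = 1, k = Inf))
  est <- stats::coef(fit)
  structure(
    list(alpha = unname(est["alpha"]), k = unname(est["k"]),
         means = means, fit = fit),
    class = "bn_decay_fit")
}

#' @export
print.bn_decay_fit <- function(x, ...) {
  cat("Robustness decay fit: y = alpha + (1 - alpha) * exp(-k (x - 1))\n")
  cat(sprintf("  alpha = %.4f (asymptotic robustness)\n", x$alpha))
  cat(sprintf("  k     = %.4f (decay rate)\n", x$k))
  cat(sprintf("  fitted to %d attractor-count bins\n", nrow(x$means)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the robustness decay fit
#'
#' @param x A `bn_decay_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter with `term`, `estimate`,
#'   `std.error`; `glance()`: a one-row tibble with `alpha`, `k`, `n_bins`,
#'   `sigma`, `deviance`.
#' @exportS3Method generics::tidy
tidy.bn_decay_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s),
                 estimate = s[, "Estimate"],
                 std.error = s[, "Std. Error"])
}

#' @rdname tidy.bn_decay_fit
#' @exportS3Method generics::glance
glance.bn_decay_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, k = x$k, n_bins = nrow(x$means),
                 sigma = summary(x$fit)$sigma,
                 deviance = stats::deviance(x$fit))
}

#' Plot experiment results
#'
#' `plot_complexity_ecdf()` shows the cumulative distribution of discovered
#' attractor counts stratified by module count; `plot_robustness_decay()`
#' shows mean robustness against attractor count per module count, with the
#' fitted decay curve overlaid when a `bn_decay_fit` is supplied.
#'
#' @param records Tibble from [run_experiment()].
#' @param fit Optional `bn_decay_fit` to overlay.
#' @return A ggplot object.
#' @export
plot_complexity_ecdf <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = n_attractors_found,
                               colour = factor(m))) +
    ggplot2::stat_ecdf(pad = FALSE) +
    ggplot2::labs(x = "number of attractors found",
                  y = "cumulative fraction of networks",
                  colour = "modules") +
    ggplot2::theme_minimal()
}

#' @rdname plot_complexity_ecdf
#' @export
plot_robustness_decay <- function(records, fit = NULL) {
  by_bin <- summarize_experiment(records)$by_bin
  p <- ggplot2::ggplot(by_bin,
                       ggplot2::aes(x = n_attractors_found,
                                    y = mean_robustness,
                                    colour = factor(m))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of attractors found",
                  y = "mean phenotypical robustness",
                  colour = "modules") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xs <- seq(min(by_bin$n_attractors_found),
              max(by_bin$n_attractors_found), length.out = 200)
    curve <- tibble::tibble(
      x = xs, y = fit$alpha + (1 - fit$alpha) * exp(-fit$k * (xs - 1)))
    p <- p + ggplot2::geom_line(
      data = curve,
      ggplot2::aes(x = x, y = y),
      inherit.aes = FALSE, linetype = "dashed")
  }
  p
}

#' @rdname plot_complexity_ecdf
#' @param object A `bn_decay_fit`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.bn_decay_fit <- function(object, ...) {
  xs <- seq(min(object$means$x), max(object$means$x), length.out = 200)
  curve <- tibble::tibble(
    x = xs, y = object$alpha + (1 - object$alpha) * exp(-object$k * (xs - 1)))
  ggplot2::ggplot(object$means, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, linetype = "dashed") +
    ggplot2::labs(x = "number of attractors",
                  y = "mean phenotypical robustness") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
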