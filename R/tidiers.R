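#' Tidiers and plots for motifroles results
#'
#' `tidy()` methods return long-format tibbles ready for dplyr/ggplot2;
#' `glance()` methods return one-row (or one-row-per-metric) summaries;
#' `autoplot()` methods give quick diagnostic plots.
#'
#' @param x A `role_fp`, `motif_fp`, `directed_clustering` or
#'   `null_ensemble` object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy role_fp
#' @export
tidy.role_fp <- function(x, ...) {
  out <- tidyr::pivot_longer(as_tibble(x), dplyr::starts_with("role_"),
                             names_to = "role_id", names_prefix = "role_",
                             names_transform = as.integer, values_to = "count")
  out$flavor <- fp_flavor(x)
  out
}

#' @rdname tidiers
#' @method tidy motif_fp
#' @export
tidy.motif_fp <- function(x, ...) {
  out <- tidyr::pivot_longer(as_tibble(x), dplyr::starts_with("motif_"),
                             names_to = "motif_id", names_prefix = "motif_",
                             names_transform = as.integer, values_to = "count")
  out$flavor <- fp_flavor(x)
  out
}

#' @rdname tidiers
#' @method glance role_fp
#' @export
glance.role_fp <- function(x, ...) {
  m <- fp_matrix(x)
  tibble(
    flavor = fp_flavor(x),
    n_nodes = ncol(m),
    total_participations = sum(m),
    busiest_node = x$label[which.max(colSums(m))]
  )
}

#' @rdname tidiers
#' @method tidy directed_clustering
#' @export
tidy.directed_clustering <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), dplyr::starts_with("C_"),
                      names_to = "subtype", names_prefix = "C_",
                      values_to = "coefficient")
}

#' @rdname tidiers
#' @method glance directed_clustering
#' @export
glance.directed_clustering <- function(x, ...) {
  tidyr::pivot_wider(
    attr(x, "global"),
    names_from = "subtype",
    values_from = c("mean_all", "mean_defined", "n_defined"),
    names_glue = "{.value}_{subtype}"
  )
}

#' @rdname tidiers
#' @method tidy null_ensemble
#' @export
tidy.null_ensemble <- function(x, ...) {
  purrr::imap_dfr(x$summary, function(s, nm) {
    dplyr::mutate(s, family = nm, .before = 1)
  })
}

#' @rdname tidiers
#' @method glance null_ensemble
#' @export
glance.null_ensemble <- function(x, ...) {
  s <- tidy(x)
  tibble(
    n_random = x$n_random,
    seed = x$seed,
    n_metrics = nrow(s),
    n_above_null = sum(s$observed > s$null_mean),
    min_ratio = min(ifelse(s$null_mean > 0, s$observed / s$null_mean, NA),
                    na.rm = TRUE),
    max_ratio = max(ifelse(s$null_mean > 0, s$observed / s$null_mean, NA),
                    na.rm = TRUE)
  )
}

#' @rdname tidiers
#' @param object Object to plot.
#' @method autoplot role_fp
#' @export
autoplot.role_fp <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$role_id, y = .data$label,
                                 fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "role id", y = NULL, fill = "count",
      title = sprintf("%s motif-role fingerprints", fp_flavor(object))
    )
}

#' @rdname tidiers
#' @method autoplot directed_clustering
#' @export
autoplot.directed_clustering <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$subtype, y = .data$coefficient)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "clustering subtype", y = "per-node coefficient")
}

#' @rdname tidiers
#' @method autoplot null_ensemble
#' @export
autoplot.null_ensemble <- function(object, ...) {
  s <- tidy(object)
  reps <- purrr::imap_dfr(object$summary, function(su, nm) {
    vals <- purrr::map_dfr(object$replicates, function(r) {
      v <- if (nm == "transitivity") unlist(r$transitivity) else r$clustering
      tibble(metric = su$metric, value = as.numeric(v))
    })
    vals$family <- nm
    vals
  })
  ggplot2::ggplot(reps, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, size = 0.8) +
    ggplot2::geom_point(
      data = s,
      ggplot2::aes(y = .data$observed), shape = 21, size = 3,
      fill = "white", color = "black"
    ) +
    ggplot2::facet_wrap(~family, scales = "free") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "value",
                  title = "observed (circles) vs degree-preserving null (dots)")
}
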