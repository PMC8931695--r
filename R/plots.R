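#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_hline
#'   geom_errorbar facet_wrap labs theme_minimal position_dodge
NULL

#' Plot class endorsement profiles
#'
#' Item endorsement probability per latent class, the standard profile plot
#' for inspecting a class solution.
#'
#' @param object An `lca_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lca_fit <- function(object, ...) {
  d <- as_tibble(object$endorse, rownames = NULL) |>
    mutate(class = factor(paste0("class ", seq_len(object$K),
                                 " (", round(100 * object$weights, 1), "%)"))) |>
    pivot_longer(-"class", names_to = "item", values_to = "probability") |>
    mutate(item = factor(.data$item, levels = object$item_labels))
  ggplot(d, aes(x = .data$item, y = .data$probability,
                group = .data$class, colour = .data$class)) +
    geom_line() + geom_point(size = 1) +
    labs(x = NULL, y = "endorsement probability", colour = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot information criteria across class solutions
#'
#' @param object An `lca_enumeration`.
#' @param ... Unused.
#' @export
autoplot.lca_enumeration <- function(object, ...) {
  d <- object$summary |>
    select("K", "AIC", "BIC", "ABIC") |>
    pivot_longer(-"K", names_to = "criterion", values_to = "value")
  ggplot(d, aes(x = .data$K, y = .data$value, colour = .data$criterion)) +
    geom_line() + geom_point() +
    labs(x = "number of classes", y = "information criterion", colour = NULL) +
    theme_minimal()
}

#' Plot standardized loadings of a coactivation network
#'
#' @param object A `cfa_fit`.
#' @param group Group whose standardized solution is drawn.
#' @param ... Unused.
#' @export
autoplot.cfa_fit <- function(object, group = object$groups[1], ...) {
  std <- standardized_loadings(object, group)
  lam <- object$mats[[match(group, object$groups)]]$Lambda
  fac <- colnames(lam)[apply(lam != 0, 1L, which.max)]
  d <- tibble(indicator = names(std), loading = unname(std), factor = fac)
  ggplot(d, aes(x = stats::reorder(.data$indicator, .data$loading),
                y = .data$loading, fill = .data$factor)) +
    geom_col() +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "standardized loading", fill = NULL) +
    theme_minimal()
}

#' Forest plot of latent-mean contrasts
#'
#' @param object A tibble from [compare_latent_means()].
#' @param ... Unused.
#' @export
autoplot.latent_contrast_tbl <- function(object, ...) {
  d <- mutate(object,
              label = paste(.data$group1, "vs", .data$group2),
              lo = .data$estimate - 1.96 * .data$se,
              hi = .data$estimate + 1.96 * .data$se)
  ggplot(d, aes(x = .data$estimate, y = .data$label)) +
    geom_point() +
    geom_errorbar(aes(xmin = .data$lo, xmax = .data$hi), width = 0.2) +
    geom_hline(xintercept = 0, linetype = 2, colour = "grey50") +
    facet_wrap(~ .data$factor, scales = "free_y") +
    labs(x = "latent mean difference (group2 - group1)", y = NULL) +
    theme_minimal()
}
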