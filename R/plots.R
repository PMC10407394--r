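#' Clone-size histogram
#'
#' Bar chart of clone sizes per sample, split by clone mutation status —
#' the expanded-clone inventory at a glance.
#'
#' @param rearr A clone-called tibble from [call_clones()].
#' @param min_size Smallest clone size shown (default 1 shows singletons).
#' @return A ggplot object.
#' @export
plot_clone_sizes <- function(rearr, min_size = 1L) {
  clones <- summarize_clones(rearr) |>
    dplyr::filter(.data$clone_size >= min_size)
  ggplot2::ggplot(clones,
                  ggplot2::aes(x = factor(.data$clone_size),
                               fill = .data$clone_status)) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample_id)) +
    ggplot2::labs(x = "clone size (cells)", y = "number of clones",
                  fill = "clone status") +
    ggplot2::theme_minimal()
}

#' Per-cell V-gene mutation frequency by sample
#'
#' Jittered per-cell mutation frequencies with unmutated cells (at most one
#' difference to the germline) distinguished from mutated ones.
#'
#' @param rearr A mutation-profiled tibble from [profile_mutations()].
#' @return A ggplot object.
#' @export
plot_mutation_frequency <- function(rearr) {
  dat <- dplyr::filter(rearr, !is.na(.data$v_mutation_freq_pct))
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = .data$sample_id,
                               y = .data$v_mutation_freq_pct,
                               colour = .data$mutation_status)) +
    ggplot2::geom_jitter(width = 0.2, height = 0, alpha = 0.7) +
    ggplot2::labs(x = "sample", y = "V-gene mutation frequency (%)",
                  colour = "status") +
    ggplot2::theme_minimal()
}
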