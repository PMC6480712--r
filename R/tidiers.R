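# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.interface_energy_report <- function(x, ...) x$energies

#' @export
glance.interface_energy_report <- function(x, ...) {
  tibble::tibble(mean = x$mean, sd = x$sd, n_frames = nrow(x$energies),
                 cutoff = x$model$cutoff)
}

#' @export
tidy.ala_scan_result <- function(x, ...) {
  tibble::tibble(chainId = x$residues$chainId, resSeq = x$residues$resSeq,
                 E_wt = x$E_wt, E_mut = x$E_mut, contribution = x$contribution)
}

#' @export
glance.ala_scan_result <- function(x, ...) {
  tibble::tibble(n_mutated = nrow(x$residues), E_wt = x$E_wt,
                 E_mut = x$E_mut, contribution = x$contribution)
}

#' @export
glance.stability_window <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
tidy.rotamer_states <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.rotamer_states <- function(x, ...) state_occupancy(x)

#' @export
glance.distance_trace <- function(x, ...) {
  s <- attr(x, "summary")
  if (is.null(s)) s <- summarize_trace(x[[setdiff(names(x), c("frame", "time"))[1]]])
  s
}

#' Plot methods for trace objects
#'
#' `autoplot()` renders RMSD traces, chi1 traces (with the cis/trans
#' threshold line), distance traces and per-frame interface energies as
#' ggplot2 line plots, and contact fingerprints as a bar chart.
#'
#' @param object a trace or report object.
#' @param ... unused.
#' @return a ggplot.
#' @name autoplot-rotadimer
NULL

#' @rdname autoplot-rotadimer
#' @export
autoplot.rmsd_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$rmsd)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "time (ns)", y = "RMSD (Å)",
                  title = paste0("RMSD vs ", attr(object, "reference"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-rotadimer
#' @export
autoplot.chi1_trace <- function(object, ...) {
  res <- attr(object, "residue")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$chi1)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ROTAMER_THRESHOLD, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 360),
                                breaks = c(0, 90, 180, 240, 300, 360)) +
    ggplot2::labs(x = "time (ns)", y = "χ1 (deg)",
                  title = if (!is.null(res))
                    sprintf("%s%d χ1", res$resName, res$resSeq) else "χ1") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-rotadimer
#' @export
autoplot.distance_trace <- function(object, ...) {
  col <- intersect(c("min_dist", "dist"), names(object))[1]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data[[col]])) +
    ggplot2::geom_line(color = "darkorange") +
    ggplot2::labs(x = "time (ns)", y = "distance (Å)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-rotadimer
#' @export
autoplot.interface_energy_report <- function(object, ...) {
  ggplot2::ggplot(object$energies, ggplot2::aes(x = .data$time, y = .data$energy)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::geom_hline(yintercept = object$mean, linetype = "dashed") +
    ggplot2::labs(x = "time (ns)", y = "interface energy (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-rotadimer
#' @export
autoplot.contact_frequency <- function(object, ...) {
  object$res_label <- ifelse(is.na(object$label),
                             paste0(object$resName, object$resSeq),
                             paste0(object$resName, object$resSeq, "^", object$label))
  ggplot2::ggplot(object, ggplot2::aes(x = stats::reorder(.data$res_label,
                                                          -.data$fraction),
                                       y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of frames in contact") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
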