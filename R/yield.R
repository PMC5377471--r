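# Overyielding: mixture performance relative to the best monoculture.

#' Observed yield statistic D_max
#'
#' Compares mixture performance to the maximally performing species in
#' monoculture (transgressive overyielding).  Responses are first mapped to
#' a common performance scale: identity when larger values mean more
#' process (\code{"higher_is_more"}), negation when smaller values do
#' (\code{"lower_is_more"}, e.g. bromide drawdown where negative values
#' indicate increased bioirrigation).  For each mixture replicate
#' \deqn{D = (P_mix - max_s \bar P_mono(s)) / max_s \bar P_mono(s),}
#' and the estimate is the replicate mean with a Student-t 95\% confidence
#' interval.  \code{D_max > 0} indicates overyielding (the mixture
#' outperforms expectations based on the corresponding monocultures),
#' \code{D_max < 0} underyielding.
#'
#' @param mixture_values response values of the mixture replicates (>= 2).
#' @param monoculture_means named vector of monoculture mean responses
#'   (>= 1 species).
#' @param response_direction \code{"higher_is_more"} or
#'   \code{"lower_is_more"}.
#' @param conf_level confidence level of the t-interval.
#' @return Object of class \code{"d_max"}: \code{D_max}, \code{ci_lo},
#'   \code{ci_hi}, \code{replicate_values}, \code{best_monoculture} (name),
#'   \code{n}.
#' @examples
#' d_max(c(8, 9, 7, 8, 8), c(A = 10, B = 6))  # underyielding, -0.2
#' @export
d_max <- function(mixture_values,
                  monoculture_means,
                  response_direction = c("higher_is_more", "lower_is_more"),
                  conf_level = 0.95) {
  response_direction <- match.arg(response_direction)
  stopifnot(length(mixture_values) >= 2, length(monoculture_means) >= 1,
            conf_level > 0, conf_level < 1)
  flip <- if (response_direction == "lower_is_more") -1 else 1
  p_mix <- flip * mixture_values
  p_mono <- flip * monoculture_means
  best <- max(p_mono)
  if (best == 0) {
    stop("best monoculture performance is zero: D_max undefined")
  }
  d <- (p_mix - best) / best
  n <- length(d)
  se <- sd(d) / sqrt(n)
  tq <- qt(1 - (1 - conf_level) / 2, df = n - 1)
  structure(list(D_max = mean(d),
                 ci_lo = mean(d) - tq * se,
                 ci_hi = mean(d) + tq * se,
                 replicate_values = d,
                 best_monoculture = names(which.max(p_mono))[1],
                 n = n, conf_level = conf_level),
            class = "d_max")
}

#' @export
print.d_max <- function(x, ...) {
  cat(sprintf("D_max = %.3f [%.3f, %.3f] (%g%% CI, n = %d)\n",
              x$D_max, x$ci_lo, x$ci_hi, 100 * x$conf_level, x$n))
  cat(sprintf("  best monoculture: %s; %s\n", x$best_monoculture,
              if (x$D_max > 0) "overyielding (D_max > 0)"
              else if (x$D_max < 0) "underyielding (D_max < 0)"
              else "parity"))
  invisible(x)
}

#' D_max from a tidy response table
#'
#' Computes \code{\link{d_max}} for each response in a tidy table with
#' columns \code{treatment}, \code{response}, \code{response_name}, using
#' one treatment level as the mixture and the others as monocultures.
#'
#' @param data tidy data.frame of responses.
#' @param mixture_label treatment level holding the mixture (default "Mix").
#' @param directions named vector mapping \code{response_name} to a
#'   response direction (default \code{"higher_is_more"} for unnamed
#'   responses).
#' @param conf_level confidence level.
#' @return data.frame: \code{response_name, D_max, ci_lo, ci_hi, n}.
#' @export
d_max_table <- function(data, mixture_label = "Mix", directions = NULL,
                        conf_level = 0.95) {
  stopifnot(is.data.frame(data),
            all(c("treatment", "response", "response_name") %in% names(data)))
  out <- lapply(split(data, data$response_name), function(d) {
    rn <- d$response_name[1]
    dir <- if (!is.null(directions) && rn %in% names(directions)) {
      directions[[rn]]
    } else "higher_is_more"
    mix <- d$response[d$treatment == mixture_label]
    mono <- d[d$treatment != mixture_label, ]
    means <- tapply(mono$response, mono$treatment, mean)
    dm <- d_max(mix, means[!is.na(means)], dir, conf_level)
    data.frame(response_name = rn, D_max = dm$D_max, ci_lo = dm$ci_lo,
               ci_hi = dm$ci_hi, n = dm$n, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
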