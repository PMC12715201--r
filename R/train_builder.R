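#' @include AllClasses.R
NULL

#' Construct an adaptive IPI train rule
#'
#' @param ratio_beta abrupt-change ratio against the running median IPI
#'   (default 2.5).
#' @param window_m number of trailing IPIs in the running median
#'   (default 5).
#' @param absolute_cap hard IPI cap in seconds (default 0.5).
#' @param min_pulses minimum pulses for a train to be kept (default 3).
#' @return a [TrainRule-class].
#' @export
trainRule <- function(ratio_beta = 2.5, window_m = 5L,
                      absolute_cap = 0.5, min_pulses = 3L) {
  new("TrainRule", ratio_beta = ratio_beta, window_m = as.integer(window_m),
      absolute_cap = absolute_cap, min_pulses = as.integer(min_pulses))
}

#' Inter-pulse intervals of a sorted event sequence
#'
#' @param times strictly increasing pulse times in seconds.
#' @return numeric vector of `length(times) - 1` intervals (seconds).
#' @examples
#' computeIpis(c(0, 0.010, 0.025))   # 10 and 15 ms
#' @export
computeIpis <- function(times) {
  if (length(times) < 2L) return(numeric(0))
  d <- diff(times)
  if (any(d <= 0)) stop("pulse times must be strictly increasing")
  d
}

#' Classify a pulse train by its mean inter-pulse interval
#'
#' Buzz for mean IPI below 4.9 ms, echolocation click above 15.5 ms,
#' burst pulse for the intermediate band; the boundary values belong to
#' the burst-pulse band. Vectorized.
#'
#' @param mean_ipi mean IPI in seconds (positive).
#' @return character vector: `"buzz"`, `"burst_pulse"` or `"click"`.
#' @examples
#' classifyTrain(c(0.00213, 0.01061, 0.08084))
#' @export
classifyTrain <- function(mean_ipi) {
  if (any(!is.finite(mean_ipi)) || any(mean_ipi <= 0))
    stop("mean_ipi must be positive and finite")
  ifelse(mean_ipi < 0.0049, "buzz",
         ifelse(mean_ipi > 0.0155, "click", "burst_pulse"))
}

#' Group pulse events into trains with the adaptive IPI rule
#'
#' Walks the time-sorted events left to right. A pulse extends the open
#' train iff its IPI is at most
#' `min(absolute_cap, ratio_beta * median(last window_m IPIs))` — a
#' gradual IPI change keeps the train open, an abrupt increase (or any
#' gap beyond the cap) terminates it. The first IPI of a train is only
#' checked against the cap. Trains shorter than `min_pulses` are
#' discarded; every retained pulse belongs to exactly one train. Each
#' train is labeled by [classifyTrain()] on its mean IPI.
#'
#' @param events event data.frame ([detectPulses()] output) or any
#'   data.frame with a numeric `time` column, time-sorted.
#' @param rule a [TrainRule-class].
#' @param source_id provenance string stored on each train.
#' @return list of [PulseTrain-class]; attribute `n_discarded` counts the
#'   pulses dropped with sub-minimum trains.
#' @export
segmentTrains <- function(events, rule = trainRule(), source_id = "") {
  if (is.null(events) || nrow(events) == 0L) {
    out <- list(); attr(out, "n_discarded") <- 0L; return(out)
  }
  t <- events$time
  if (any(diff(t) <= 0)) stop("events must be sorted with strictly increasing times")
  n <- length(t)
  groups <- list()
  cur <- 1L          # indices of the open train
  cur_ipis <- numeric(0)
  for (i in seq_len(n)[-1L]) {
    ipi <- t[i] - t[cur[length(cur)]]
    thr <- if (length(cur_ipis) == 0L) rule@absolute_cap else
      min(rule@absolute_cap,
          rule@ratio_beta * stats::median(utils::tail(cur_ipis, rule@window_m)))
    if (ipi <= thr) {
      cur <- c(cur, i)
      cur_ipis <- c(cur_ipis, ipi)
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- i
      cur_ipis <- numeric(0)
    }
  }
  groups[[length(groups) + 1L]] <- cur

  keep <- vapply(groups, length, integer(1)) >= rule@min_pulses
  n_discarded <- sum(vapply(groups[!keep], length, integer(1)))
  trains <- lapply(groups[keep], function(idx) {
    ev <- events[idx, , drop = FALSE]
    ip <- diff(ev$time)
    new("PulseTrain", events = ev, ipis = ip,
        label = classifyTrain(mean(ip)), source_id = source_id)
  })
  attr(trains, "n_discarded") <- as.integer(n_discarded)
  trains
}

#' Remove trains listed for manual exclusion
#'
#' The field workflow removes trains with heavy reverberation or multiple
#' animals by eye; this hook applies such an exclusion list (train serial
#' indices) after automatic segmentation.
#'
#' @param trains list of [PulseTrain-class].
#' @param exclude integer indices to drop.
#' @return the filtered list.
#' @export
excludeTrains <- function(trains, exclude = integer(0)) {
  if (!length(exclude)) return(trains)
  trains[-exclude]
}
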