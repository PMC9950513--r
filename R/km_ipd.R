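#' Digitized Kaplan-Meier curve
#'
#' Container for coordinates read off a published KM figure: ordered
#' (time, survival) pairs. Times must be strictly increasing and
#' probabilities in \[0, 1\]. A curve not starting at (0, 1) has the origin
#' prepended; small digitization jitter that breaks monotonicity is repaired
#' by isotonic clamping (running minimum) with a warning.
#'
#' @param time Times in months.
#' @param survival Survival probabilities.
#' @param arm Optional arm label.
#' @return A `digitized_curve`: data frame with columns `time`, `survival`.
#' @export
digitized_curve <- function(time, survival, arm = NULL) {
  stopifnot(length(time) == length(survival), length(time) >= 1)
  o <- order(time)
  time <- as.numeric(time[o]); survival <- as.numeric(survival[o])
  if (any(duplicated(time))) stop("duplicated times in digitized curve", call. = FALSE)
  if (any(time < 0)) stop("negative time in digitized curve", call. = FALSE)
  if (any(survival < 0 | survival > 1))
    stop("survival probabilities outside [0, 1]", call. = FALSE)
  if (time[1] > 0) { time <- c(0, time); survival <- c(1, survival) }
  if (survival[1] != 1) {
    warning("first digitized point below 1 at t = 0; reset to 1", call. = FALSE)
    survival[1] <- 1
  }
  if (is.unsorted(rev(survival))) {
    warning("digitized survival not non-increasing; isotonic clamp applied",
            call. = FALSE)
    survival <- cummin(survival)
  }
  structure(data.frame(time = time, survival = survival),
            class = c("digitized_curve", "data.frame"), arm = arm)
}

#' Numbers-at-risk table
#'
#' @param time Interval boundary times (months), strictly increasing,
#'   starting at 0.
#' @param n_risk Number at risk at each boundary; non-negative and
#'   non-increasing, first entry equal to the arm size.
#' @return A `risk_table`: data frame with columns `time`, `n_risk`.
#' @export
risk_table <- function(time, n_risk) {
  stopifnot(length(time) == length(n_risk), length(time) >= 1)
  o <- order(time)
  time <- as.numeric(time[o]); n_risk <- as.numeric(n_risk[o])
  if (any(n_risk < 0)) stop("negative number at risk", call. = FALSE)
  if (is.unsorted(rev(n_risk)))
    stop("number at risk increases over time: inconsistent risk table",
         call. = FALSE)
  structure(data.frame(time = time, n_risk = n_risk),
            class = c("risk_table", "data.frame"))
}

#' Kaplan-Meier estimate from individual patient data
#'
#' Product-limit estimator (via [survival::survfit()]) returned in the same
#' (time, survival) layout as a [digitized_curve()], with the origin (0, 1)
#' included. Drops occur only at event times.
#'
#' @param ipd Data frame with columns `time` and `event` (0/1), e.g. a
#'   [guyot_reconstruct()] or [simulate_ipd()] result.
#' @return A `digitized_curve` with one row per distinct observed time.
#' @export
km_estimate <- function(ipd) {
  stopifnot(is.data.frame(ipd), all(c("time", "event") %in% names(ipd)))
  if (nrow(ipd) == 0) stop("empty IPD", call. = FALSE)
  if (sum(ipd$event) == 0) stop("no events in IPD", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  digitized_curve(c(0, fit$time), c(1, fit$surv), arm = attr(ipd, "arm"))
}

#' Evaluate a step curve at arbitrary times
#'
#' Right-continuous step interpolation of a (digitized or KM) curve:
#' \eqn{S(t)} equals the survival at the last tabulated time \eqn{\le t}.
#'
#' @param curve A `digitized_curve`.
#' @param t Times (months).
#' @return Survival probabilities at `t`.
#' @export
km_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, 1, curve$survival[pmax(idx, 1)])
}

#' Reconstruct individual patient data from a digitized KM curve
#'
#' Recovers pseudo individual patient data from digitized survival
#' coordinates plus a numbers-at-risk table, following the iterative
#' interval-accounting scheme of Guyot and colleagues: within each risk
#' interval the number censored is guessed from the drop in numbers at risk
#' relative to the drop in survival, censoring times are spread uniformly
#' across the interval, per-coordinate event counts are solved so the
#' reconstructed product-limit estimate tracks the digitized probabilities,
#' and the censoring guess is adjusted until the numbers at risk at the next
#' boundary are matched. Subjects still at risk at the last coordinate are
#' administratively censored there. The algorithm is deterministic.
#'
#' @param curve A [digitized_curve()].
#' @param risk A [risk_table()] whose boundaries lie within the curve's time
#'   span. If `NULL`, a no-censoring reconstruction is used (every drop is
#'   events only) and the result is flagged with
#'   `attr(, "no_risk_table") = TRUE`.
#' @param total_events Optional total event count; when given, censoring in
#'   the final interval is adjusted so the reconstructed number of events
#'   comes within +/- 2 of it.
#' @return Data frame with columns `time`, `event`, class
#'   `reconstructed_ipd`; subject count equals the first risk-table entry.
#' @references Guyot P, Ades AE, Ouwens MJNM, Welton NJ. Enhanced secondary
#'   analysis of survival data. BMC Med Res Methodol 2012;12:9.
#' @export
guyot_reconstruct <- function(curve, risk = NULL, total_events = NULL) {
  stopifnot(inherits(curve, "digitized_curve"))
  tS <- curve$time; S <- curve$survival; J <- length(tS)

  if (is.null(risk)) {
    # no-censoring fallback: choose n so drops round to integers reasonably
    n0 <- attr(curve, "n") %||% 100L
    d <- round(-diff(c(1, S)) * n0)
    times <- rep(tS, d)
    left <- n0 - sum(d)
    ipd <- data.frame(time = c(times, rep(max(tS), left)),
                      event = c(rep(1L, length(times)), rep(0L, left)))
    attr(ipd, "no_risk_table") <- TRUE
    class(ipd) <- c("reconstructed_ipd", "data.frame")
    return(ipd)
  }
  stopifnot(inherits(risk, "risk_table"))
  tR <- risk$time; nR <- risk$n_risk; I <- length(tR)
  if (min(tR) < min(tS) - 1e-9 || max(tR) > max(tS) + 1e-9)
    stop("risk-table boundaries outside the digitized time span", call. = FALSE)

  # map risk intervals to coordinate indices
  lower <- vapply(seq_len(I), function(i) which(tS >= tR[i] - 1e-9)[1], integer(1))
  upper <- c(vapply(seq_len(I - 1), function(i) {
    w <- which(tS < tR[i + 1] - 1e-9); tail(w, 1)
  }, integer(1)), J)

  n_int <- I
  d <- integer(J)          # events at coordinate j
  cen <- integer(J)        # censorings in [t_j, t_{j+1})
  n_hat <- numeric(J + 1)
  n_hat[lower[1]] <- nR[1]

  run_interval <- function(i, ncen, n_start, s_last, d, cen) {
    lo <- lower[i]; up <- upper[i]
    t_end <- if (i < n_int) tR[i + 1] else tS[J]
    if (ncen > 0) {
      cen_t <- tR[i] + seq_len(ncen) * (t_end - tR[i]) / (ncen + 1)
    } else cen_t <- numeric(0)
    n_j <- n_start
    for (j in lo:up) {
      dj <- round(n_j * (1 - S[j] / s_last))
      dj <- max(0L, min(dj, n_j))
      if (dj > 0 && n_j > 0) s_last <- s_last * (1 - dj / n_j)
      nxt <- if (j < J) tS[j + 1] else Inf
      cj <- sum(cen_t >= tS[j] - 1e-12 & cen_t < nxt - 1e-12)
      cj <- min(cj, n_j - dj)
      d[j] <- dj; cen[j] <- cj
      n_j <- n_j - dj - cj
    }
    list(n_end = n_j, s_last = s_last, d = d, cen = cen)
  }

  s_last <- 1
  for (i in seq_len(n_int)) {
    lo <- lower[i]
    n_start <- if (i == 1) nR[1] else n_hat[lo]
    if (i < n_int) {
      expected <- n_start * S[lower[i + 1]] / max(S[lo], .Machine$double.eps)
      ncen <- max(0L, round(expected) - nR[i + 1])
      res <- NULL
      for (iter in 1:30) {
        res <- run_interval(i, ncen, n_start, s_last, d, cen)
        gap <- res$n_end - nR[i + 1]
        if (gap == 0) break
        ncen2 <- max(0L, ncen + gap)
        if (ncen2 == ncen) break
        ncen <- ncen2
      }
      d <- res$d; cen <- res$cen; s_last <- res$s_last
      n_hat[lower[i + 1]] <- res$n_end
    } else {
      ncen <- 0L
      res <- run_interval(i, ncen, n_start, s_last, d, cen)
      if (!is.null(total_events)) {
        # res$d covers all intervals, so sum(res$d) is the overall event count;
        # censoring earlier in the last interval removes subjects before they
        # can contribute events, so the count is non-increasing in ncen
        best <- res; best_gap <- abs(sum(res$d) - total_events)
        while (sum(res$d) > total_events && ncen < n_start) {
          ncen <- ncen + 1L
          res <- run_interval(i, ncen, n_start, s_last, d, cen)
          gap <- abs(sum(res$d) - total_events)
          if (gap < best_gap) { best <- res; best_gap <- gap }
        }
        res <- best
      }
      d <- res$d; cen <- res$cen
    }
  }

  # if the digitized drops round to fewer events than reported, convert
  # trailing administrative censorings (which carry no curve information)
  # into events at the final coordinate
  if (!is.null(total_events) && sum(d) < total_events) {
    leftover <- nR[1] - sum(d) - sum(cen)
    extra <- min(total_events - sum(d), max(leftover, 0))
    d[J] <- d[J] + extra
  }
  times <- c(rep(tS, d), unlist(lapply(seq_len(J), function(j) {
    if (cen[j] == 0) return(numeric(0))
    nxt <- if (j < J) tS[j + 1] else tS[J]
    tS[j] + seq_len(cen[j]) * (nxt - tS[j]) / (cen[j] + 1)
  })))
  events <- c(rep(1L, sum(d)), rep(0L, sum(cen)))
  left <- nR[1] - length(times)
  if (left > 0) {
    times <- c(times, rep(tS[J], left))
    events <- c(events, rep(0L, left))
  }
  o <- order(times, -events)
  ipd <- data.frame(time = times[o], event = events[o])
  attr(ipd, "arm") <- attr(curve, "arm")
  class(ipd) <- c("reconstructed_ipd", "data.frame")
  ipd
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write IPD as delimited text
#'
#' Plain CSV with columns `time,event` (event in \{0, 1\}).
#'
#' @param ipd Data frame with `time` and `event`.
#' @param path File path.
#' @return `read_ipd()` returns the IPD data frame; `write_ipd()` returns
#'   `path` invisibly.
#' @export
write_ipd <- function(ipd, path) {
  write.csv(ipd[, c("time", "event")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ipd
#' @export
read_ipd <- function(path) {
  ipd <- read.csv(path)
  stopifnot(all(c("time", "event") %in% names(ipd)))
  class(ipd) <- c("reconstructed_ipd", "data.frame")
  ipd
}
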