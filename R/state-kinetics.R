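#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a StateSeries
#'
#' @param times uniformly spaced timestamps (ps).
#' @param labels character labels, one per time.
#' @return a [StateSeries-class].
#' @export
stateSeries <- function(times, labels) {
  new("StateSeries", times = times, labels = as.character(labels))
}

#' Classify hydrophobic-pocket snapshots from (d, Q)
#'
#' Four conformational/hydration states: wet open (d > 7 A and Q > 8 e),
#' wet half-open (5 < d < 7 and Q > 8), dry half-open (5 < d < 7 and
#' Q < 4), closed (d < 5 and Q < 4). Snapshots falling in none of the
#' boxes (the 4 <= Q <= 8 gap, a threshold value of d, or e.g. d > 7 with
#' Q < 4) are labelled "boundary" and later resolved by temporal proximity
#' ([resolveBoundaries()]).
#'
#' @param d jaw-separation gauge (A), vectorised.
#' @param Q region-integrated hydration charge (e), vectorised.
#' @param dClosed,dOpen d thresholds (default 5 and 7 A).
#' @param qDry,qWet Q thresholds (default 4 and 8 e).
#' @return character vector of state labels.
#' @export
classifyHS1 <- function(d, Q, dClosed = 5, dOpen = 7, qDry = 4, qWet = 8) {
  out <- rep("boundary", length(d))
  out[d > dOpen & Q > qWet] <- "wet_open"
  out[d > dClosed & d < dOpen & Q > qWet] <- "wet_half_open"
  out[d > dClosed & d < dOpen & Q < qDry] <- "dry_half_open"
  out[d < dClosed & Q < qDry] <- "closed"
  out
}

#' Classify hydrophilic-crevice occupancy from Q
#'
#' Q plateaus at 30/40/50 e (three to five resident waters); snapshots are
#' binned to the nearest plateau within +-5 e (cut points at 35 and 45 e,
#' half-open upwards so Q = 35 is "4w"); Q outside [25, 55] is "boundary".
#'
#' @param Q hydration charge (e), vectorised.
#' @param plateaus plateau values (default c(30, 40, 50)).
#' @param halfWidth bin half-width (default 5 e).
#' @return character vector of "3w"/"4w"/"5w"/"boundary" (labels are
#'   (k)w for plateau ~ 10k e).
#' @export
classifyHS2 <- function(Q, plateaus = c(30, 40, 50), halfWidth = 5) {
  labs <- paste0(round(plateaus / 10), "w")
  out <- rep("boundary", length(Q))
  edges <- c(plateaus[1] - halfWidth,
             plateaus[-length(plateaus)] + diff(plateaus) / 2,
             plateaus[length(plateaus)] + halfWidth)
  bin <- findInterval(Q, edges, rightmost.closed = TRUE)
  ok <- bin >= 1 & bin <= length(plateaus)
  out[ok] <- labs[bin[ok]]
  out
}

#' Resolve boundary labels by temporal proximity
#'
#' Every "boundary" snapshot is assigned the label of the temporally
#' nearest classified snapshot; exact ties go to the earlier side.
#' Idempotent; never alters non-boundary labels.
#'
#' @param series a [StateSeries-class] (>= 1 non-boundary label).
#' @return a [StateSeries-class] without boundary labels.
#' @export
resolveBoundaries <- function(series) {
  lab <- series@labels
  good <- which(lab != "boundary")
  if (length(good) == 0) stop("series is all boundary; cannot resolve")
  bad <- which(lab == "boundary")
  if (length(bad)) {
    # nearest classified index; tie -> earlier (smaller index)
    posBelow <- findInterval(bad, good)
    pick <- integer(length(bad))
    for (i in seq_along(bad)) {
      b <- if (posBelow[i] >= 1) good[posBelow[i]] else NA_integer_
      a <- if (posBelow[i] < length(good)) good[posBelow[i] + 1]
           else NA_integer_
      pick[i] <- if (is.na(a)) b
                 else if (is.na(b)) a
                 else if ((bad[i] - b) <= (a - bad[i])) b else a
    }
    lab[bad] <- lab[pick]
  }
  new("StateSeries", times = series@times, labels = lab,
      metadata = series@metadata)
}

#' Extract dwell segments from a resolved state series
#'
#' Maximal constant-label runs become dwell records. The first and last
#' runs are censored (their true duration is unobserved) and short runs
#' (duration <= tMin) are excluded from the fit set, but all runs remain
#' in the table so transition tallies are unaffected.
#'
#' @param series a resolved [StateSeries-class] (no boundary labels).
#' @param tMin residence-time floor in ps (default 5); runs must exceed it
#'   to enter the fit set.
#' @return data.frame: state, start, end, duration (ps), successor
#'   (NA for the final run), censored, fit (logical: use in rate fits).
#' @export
extractDwells <- function(series, tMin = 5) {
  lab <- series@labels
  if (any(lab == "boundary"))
    stop("resolve boundaries before extracting dwells")
  t <- series@times
  n <- length(lab)
  if (n == 0) return(data.frame())
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  dt <- if (n > 1) t[2] - t[1] else 1
  # a run of k snapshots spans k*dt of trajectory time
  dur <- r$lengths * dt
  succ <- c(r$values[-1], NA)
  censored <- seq_along(r$values) %in% c(1, length(r$values))
  data.frame(state = r$values,
             start = t[starts], end = t[ends] + dt,
             duration = dur, successor = succ,
             censored = censored,
             fit = !censored & dur > tMin,
             stringsAsFactors = FALSE)
}

#' Fit an exponential residence-time model for one transition
#'
#' The empirical cumulative distribution of (t_res - tMin) over the fit-set
#' dwells of state A that end in state B is least-squares fitted by
#' 1 - exp(-t/tau); 1/tau is the A -> B rate constant. The closed-form
#' truncated-exponential estimate mean(t_res) - tMin is always reported in
#' the diagnostics (and is available as the primary estimator via
#' `method = "closed_form"`). Deterministic given the dwell set.
#'
#' @param dwells data.frame from [extractDwells()], or a numeric vector of
#'   residence times (ps).
#' @param stateA,stateB transition selector (required when `dwells` is a
#'   data.frame).
#' @param tMin residence-time floor used in the extraction (ps, default 5).
#' @param method "ls_cdf" (default) or "closed_form".
#' @return a [RateEstimate-class].
#' @export
fitRate <- function(dwells, stateA = NA_character_, stateB = NA_character_,
                    tMin = 5, method = c("ls_cdf", "closed_form")) {
  method <- match.arg(method)
  if (is.data.frame(dwells)) {
    if (is.na(stateA) || is.na(stateB))
      stop("stateA and stateB are required with a dwell table")
    tres <- dwells$duration[dwells$fit & dwells$state == stateA &
                            !is.na(dwells$successor) &
                            dwells$successor == stateB]
  } else {
    tres <- as.numeric(dwells)
  }
  n <- length(tres)
  if (n < 5)
    stop(sprintf("insufficient data: %d dwell(s) for %s -> %s (need >= 5)",
                 n, stateA, stateB))
  x <- sort(tres - tMin)
  if (any(x < 0)) stop("residence times below tMin")
  Fhat <- seq_len(n) / n
  tauCF <- mean(x)
  obj <- function(tau) sum((Fhat - (1 - exp(-x / tau)))^2)
  tau <- if (method == "closed_form") tauCF else {
    opt <- stats::optimize(obj, interval = c(tauCF / 50, tauCF * 50))
    opt$minimum
  }
  new("RateEstimate", stateA = as.character(stateA),
      stateB = as.character(stateB), tau = tau, rate = 1 / tau,
      nDwells = as.integer(n),
      diagnostics = list(tauClosedForm = tauCF,
                         residualNorm = sqrt(obj(tau) / n),
                         method = method, tMin = tMin))
}

#' Fit rate constants for every observed transition of a series
#'
#' @param series a resolved [StateSeries-class].
#' @param tMin residence-time floor (ps).
#' @param minDwells transitions with fewer fit-set dwells are skipped.
#' @return data.frame: from, to, tau (ps), rate (ps^-1), nDwells.
#' @export
fitAllRates <- function(series, tMin = 5, minDwells = 5) {
  dw <- extractDwells(series, tMin = tMin)
  pairs <- unique(dw[dw$fit & !is.na(dw$successor), c("state", "successor")])
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    tres <- dw$duration[dw$fit & dw$state == pairs$state[i] &
                        !is.na(dw$successor) &
                        dw$successor == pairs$successor[i]]
    if (length(tres) < minDwells) return(NULL)
    est <- fitRate(tres, pairs$state[i], pairs$successor[i], tMin = tMin)
    data.frame(from = pairs$state[i], to = pairs$successor[i],
               tau = est@tau, rate = est@rate, nDwells = est@nDwells,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(from = character(), to = character(),
                      tau = numeric(), rate = numeric(),
                      nDwells = integer())
  out
}

#' Transition frequencies and state populations
#'
#' @param series a resolved [StateSeries-class].
#' @return list with `counts` (matrix of A -> B label changes) and
#'   `populations` (snapshot fraction per state; sums to 1).
#' @export
transitionStats <- function(series) {
  lab <- series@labels
  if (any(lab == "boundary"))
    stop("resolve boundaries before computing transition statistics")
  states <- sort(unique(lab))
  counts <- matrix(0L, length(states), length(states),
                   dimnames = list(from = states, to = states))
  if (length(lab) > 1) {
    ch <- which(lab[-1] != lab[-length(lab)])
    for (i in ch)
      counts[lab[i], lab[i + 1]] <- counts[lab[i], lab[i + 1]] + 1L
  }
  pop <- as.numeric(table(factor(lab, levels = states))) / length(lab)
  names(pop) <- states
  list(counts = counts, populations = pop)
}
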