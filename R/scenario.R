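#' Winter-type class probabilities
#'
#' Probabilities of the three categorical winter difficulty classes used by
#' the stochastic experiments.  The baseline (10\% easy, 80\% normal, 10\%
#' difficult) reflects the observed frequency of difficult winters in
#' northernmost Finnish Lapland of roughly once per decade; easy winters are
#' assumed equally frequent (symmetric variation), the remainder are average.
#'
#' @param p_easy,p_normal,p_difficult class probabilities; each must lie in
#'   \[0, 1\] and the three must sum to 1 (within 1e-12).
#' @return An object of class `winter_probs`.
#' @export
#' @examples
#' winter_probs()                 # baseline 10/80/10
#' winter_probs(0.2, 0.6, 0.2)    # doubled perturbation frequency
winter_probs <- function(p_easy = 0.10, p_normal = 0.80, p_difficult = 0.10) {
  p <- c(easy = p_easy, normal = p_normal, difficult = p_difficult)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("winter probabilities must be finite and lie in [0, 1]", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-12)
    stop("winter probabilities must sum to 1 (got ", format(sum(p), digits = 15),
         ")", call. = FALSE)
  structure(list(p_easy = p_easy, p_normal = p_normal,
                 p_difficult = p_difficult), class = "winter_probs")
}

#' @export
print.winter_probs <- function(x, ...) {
  cat(sprintf("<winter_probs> easy %.3f / normal %.3f / difficult %.3f\n",
              x$p_easy, x$p_normal, x$p_difficult))
  invisible(x)
}

as_winter_probs <- function(x) {
  if (inherits(x, "winter_probs")) return(x)
  if (is.numeric(x) && length(x) == 3) return(winter_probs(x[1], x[2], x[3]))
  stop("cannot interpret 'probs'; give a winter_probs object or a length-3 ",
       "numeric vector (easy, normal, difficult)", call. = FALSE)
}

# run an expression with a private, seeded RNG stream, restoring the caller's
# RNG state afterwards (the scenario module owns its generator)
with_scenario_rng <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Generate a stochastic winter sequence
#'
#' Draws i.i.d. winter-type labels for each year of the horizon from the
#' given class probabilities, using a private seeded random-number stream:
#' the same `(probs, horizon, seed)` always reproduces the same sequence and
#' the caller's RNG state is left untouched.
#'
#' @param probs a [winter_probs()] object (or length-3 numeric vector).
#' @param horizon number of years (>= 1).
#' @param seed integer seed of the scenario generator.
#' @return An object of class `winter_sequence`: list with `labels`
#'   (character vector of `"easy"/"normal"/"difficult"`), `probs`, `seed`.
#' @export
#' @examples
#' s <- generate_winter_sequence(winter_probs(), horizon = 100, seed = 1)
#' table(s$labels)
generate_winter_sequence <- function(probs, horizon, seed) {
  probs <- as_winter_probs(probs)
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon < 1 ||
      horizon != round(horizon))
    stop("'horizon' must be a single integer >= 1", call. = FALSE)
  horizon <- as.integer(horizon)
  pv <- c(probs$p_easy, probs$p_normal, probs$p_difficult)
  labels <- with_scenario_rng(seed, {
    idx <- sample.int(3L, horizon, replace = TRUE, prob = pv)
    c("easy", "normal", "difficult")[idx]
  })
  structure(list(labels = labels, probs = probs, seed = as.integer(seed),
                 horizon = horizon),
            class = "winter_sequence")
}

#' @export
print.winter_sequence <- function(x, ...) {
  tb <- table(factor(x$labels, levels = c("easy", "normal", "difficult")))
  cat(sprintf("<winter_sequence> %d years (seed %d): %d easy / %d normal / %d difficult\n",
              x$horizon, x$seed, tb[["easy"]], tb[["normal"]], tb[["difficult"]]))
  invisible(x)
}

#' Expected winter type for certainty-equivalence forecasts
#'
#' The feedback optimizer replaces all unknown future winters with the winter
#' type whose physical parameters (cratering area, energy-need multiplier)
#' are closest to the probability-weighted expectation.  With a symmetric
#' distribution (easy and difficult equally likely) this is exactly the
#' normal winter.
#'
#' @param probs a [winter_probs()] object.
#' @param params model parameters, see [default_params()].
#' @return One of `"easy"`, `"normal"`, `"difficult"`.
#' @export
#' @examples
#' expected_winter(winter_probs(0.4, 0.2, 0.4))  # symmetric -> "normal"
expected_winter <- function(probs, params = default_params()) {
  probs <- as_winter_probs(probs)
  pv <- c(probs$p_easy, probs$p_normal, probs$p_difficult)
  if (abs(probs$p_easy - probs$p_difficult) < 1e-9) return("normal")
  areas <- params$winter$cratering_area[c("easy", "normal", "difficult")]
  ea <- sum(pv * areas)
  names(areas)[which.min(abs(areas - ea))]
}

#' Tabulate coded-report winter-difficulty frequencies
#'
#' Summarises a coded table of annual herding-district reports (one row per
#' district-year, 0/1 flag columns marking reported difficulties) into the
#' report-style summary: for each flag, the district-level percentage of
#' flagged years, aggregated over districts as mean, minimum and maximum,
#' together with the corresponding year counts.
#'
#' @param table data frame with columns `district`, `year` and one or more
#'   0/1 (or logical) flag columns.
#' @return A data frame with one row per flag and columns `flag`, `mean_pct`,
#'   `min_pct`, `max_pct`, `mean_count`, `min_count`, `max_count`,
#'   `n_districts`, `n_years`.  Row order of the input is irrelevant.
#' @export
#' @examples
#' tbl <- simulate_coded_reports(seed = 1)
#' tabulate_report_frequencies(tbl)
tabulate_report_frequencies <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("'table' must be a non-empty data frame", call. = FALSE)
  if (!all(c("district", "year") %in% names(table)))
    stop("'table' must have 'district' and 'year' columns", call. = FALSE)
  flags <- setdiff(names(table), c("district", "year"))
  if (!length(flags)) stop("'table' has no flag columns", call. = FALSE)

  if (is.factor(table$district)) {
    empty <- setdiff(levels(table$district), unique(as.character(table$district)))
    if (length(empty))
      warning("excluding district(s) with zero recorded years: ",
              paste(empty, collapse = ", "), call. = FALSE)
  }
  districts <- sort(unique(as.character(table$district)))
  years_per_district <- vapply(
    districts, function(d) sum(table$district == d), integer(1))

  out <- lapply(flags, function(fl) {
    v <- as.numeric(table[[fl]])
    if (any(is.na(v)) || any(v != 0 & v != 1))
      stop("flag column '", fl, "' must contain 0/1 or logical values",
           call. = FALSE)
    counts <- vapply(districts,
                     function(d) sum(v[table$district == d]), numeric(1))
    pct <- 100 * counts / years_per_district
    data.frame(flag = fl,
               mean_pct = mean(pct), min_pct = min(pct), max_pct = max(pct),
               mean_count = mean(counts), min_count = min(counts),
               max_count = max(counts),
               n_districts = length(districts),
               n_years = max(years_per_district),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# construct n per-district flagged-year counts hitting an exact min, max and
# (approximately) a target mean; deterministic given the RNG stream
target_counts <- function(n, min, max, mean, years) {
  if (n < 2) return(pmin(max, pmax(min, round(mean))))
  counts <- integer(n)
  counts[1] <- min
  counts[2] <- max
  rest <- n - 2L
  if (rest > 0) {
    want <- mean * n - min - max
    base <- floor(want / rest)
    counts[3:n] <- base
    extra <- round(want - base * rest)
    if (extra > 0) {
      bump <- sample.int(rest, extra)
      counts[2L + bump] <- counts[2L + bump] + 1L
    }
  }
  pmin(years, pmax(0L, counts))
}

#' Simulate a coded annual-report table
#'
#' Generates a synthetic stand-in for the coded content of annual herding
#' district reports: a district-by-year table of 0/1 difficulty flags whose
#' district-level summary statistics reproduce specified targets (mean,
#' minimum and maximum number of flagged years per district).  Default
#' targets follow the reported frequencies for the 20 northernmost Finnish
#' herding districts over a 30-year period: about a third of winters flagged
#' as above-average difficult, deep and icy snow roughly equally common, and
#' high mortality / weak calving / emergency feeding rare.
#'
#' @param n_districts number of districts.
#' @param years vector of herding years (start years).
#' @param targets named list of `c(min, max, mean)` flagged-year counts per
#'   flag.
#' @param seed scenario-generator seed.
#' @return Data frame with columns `district`, `year` and one 0/1 column per
#'   flag.
#' @export
simulate_coded_reports <- function(n_districts = 20,
                                   years = 1981:2010,
                                   targets = list(
                                     difficult_any     = c(3, 15, 10.05),
                                     deep_snow         = c(0, 8, 4.1),
                                     icy_snow          = c(1, 8, 3.9),
                                     high_mortality    = c(0, 5, 1.6),
                                     weak_calving      = c(0, 6, 1.5),
                                     emergency_feeding = c(0, 5, 1.2)),
                                   seed = 1L) {
  ny <- length(years)
  with_scenario_rng(seed, {
    grid <- expand.grid(year = years,
                        district = sprintf("D%02d", seq_len(n_districts)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[, c("district", "year")]
    for (fl in names(targets)) {
      tg <- targets[[fl]]
      counts <- target_counts(n_districts, tg[1], tg[2], tg[3], ny)
      counts <- sample(counts)  # shuffle which district gets which count
      v <- integer(nrow(grid))
      for (d in seq_len(n_districts)) {
        yrs <- sample.int(ny, counts[d])
        v[(d - 1L) * ny + yrs] <- 1L
      }
      grid[[fl]] <- v
    }
    grid
  })
}

#' Serialize a winter sequence
#'
#' `write_winter_sequence()` writes either a two-column CSV (`year,label`) or
#' a JSON document carrying the probabilities and seed as metadata;
#' `read_winter_sequence()` reads either format back.
#'
#' @param x a `winter_sequence`.
#' @param path output file; format chosen by extension (`.csv` or `.json`).
#' @return `write_winter_sequence()`: `path`, invisibly.
#'   `read_winter_sequence()`: a `winter_sequence` (for CSV input the
#'   probability/seed metadata is absent).
#' @export
write_winter_sequence <- function(x, path) {
  stopifnot(inherits(x, "winter_sequence"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(labels = x$labels,
           probs = list(p_easy = x$probs$p_easy, p_normal = x$probs$p_normal,
                        p_difficult = x$probs$p_difficult),
           seed = x$seed, horizon = x$horizon),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(
      data.frame(year = seq_along(x$labels), label = x$labels),
      path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_winter_sequence
#' @export
read_winter_sequence <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    structure(list(labels = j$labels,
                   probs = winter_probs(j$probs$p_easy, j$probs$p_normal,
                                        j$probs$p_difficult),
                   seed = as.integer(j$seed), horizon = length(j$labels)),
              class = "winter_sequence")
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    bad <- setdiff(unique(d$label), c("easy", "normal", "difficult"))
    if (length(bad)) stop("unknown winter labels in file: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    structure(list(labels = d$label, probs = NULL, seed = NA_integer_,
                   horizon = nrow(d)),
              class = "winter_sequence")
  }
}
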