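#' Harvest-rate series of a crawl
#'
#' The harvest rate is the fraction of fetched pages classified relevant
#' among all fetched pages. Given per-interval counts (e.g. per crawl day,
#' or per block of fetches), the per-interval value reported is the
#' cumulative harvest rate up to the end of that interval; the mean harvest
#' rate is by default the unweighted mean of those interval-end values
#' (matching day-wise averaging over a crawl's lifetime). Intervals with a
#' zero cumulative fetch count have an undefined rate and are excluded from
#' the mean. The final cumulative rate is also reported, since the mean of
#' interval-end rates is generally not the ratio of the two grand totals.
#'
#' @param counts Tibble (or data frame) with columns `fetched` and
#'   `relevant`, one row per interval, or a `crawl_result` (then intervals
#'   of `interval` fetches are formed from its records).
#' @param interval Interval width in fetches when `counts` is a
#'   `crawl_result`.
#' @return A tibble of class `harvest_series` with per-interval columns and
#'   attributes `mean_hr` and `final_hr`.
#' @export
#' @examples
#' hs <- harvest_rate(data.frame(fetched = c(10, 10), relevant = c(5, 10)))
#' attr(hs, "mean_hr")
harvest_rate <- function(counts, interval = 50L) {
  if (inherits(counts, "crawl_result")) {
    recs <- counts$records[counts$records$status == "ok", ]
    if (nrow(recs) == 0) {
      counts <- tibble::tibble(fetched = integer(), relevant = integer())
    } else {
      bin <- ceiling(seq_len(nrow(recs)) / interval)
      counts <- tibble::tibble(bin = bin, relevant = recs$indexed) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(fetched = dplyr::n(),
                         relevant = sum(.data$relevant), .groups = "drop") |>
        dplyr::select("fetched", "relevant")
    }
  }
  if (any(counts$fetched < 0) || any(counts$relevant < 0) ||
      any(counts$relevant > counts$fetched)) {
    stop_input("need 0 <= relevant <= fetched in every interval")
  }
  cum_f <- cumsum(counts$fetched)
  cum_r <- cumsum(counts$relevant)
  hr <- ifelse(cum_f > 0, cum_r / cum_f, NA_real_)
  out <- tibble::tibble(
    interval = seq_along(cum_f),
    fetched = counts$fetched, relevant = counts$relevant,
    cum_fetched = cum_f, cum_relevant = cum_r, hr = hr
  )
  class(out) <- c("harvest_series", class(out))
  attr(out, "mean_hr") <- if (all(is.na(hr))) NA_real_ else mean(hr, na.rm = TRUE)
  attr(out, "final_hr") <- if (length(hr) > 0) hr[length(hr)] else NA_real_
  out
}

#' Mean harvest rate of a series
#'
#' @param series A `harvest_series`.
#' @param type `"interval_mean"` (unweighted mean of interval-end cumulative
#'   rates, the default) or `"final"` (last cumulative rate).
#' @return A fraction in `[0, 1]`.
#' @export
mean_harvest_rate <- function(series, type = c("interval_mean", "final")) {
  type <- match.arg(type)
  if (type == "interval_mean") attr(series, "mean_hr") else attr(series, "final_hr")
}

#' Stratified seed/target split
#'
#' Withholds `target_count` URLs from a seed list as hidden targets while
#' maintaining the stratum (ccTLD) composition: targets are apportioned
#' across strata by largest remainder, so each stratum's share in the
#' target set matches its global share within one item. Selection within a
#' stratum is a seeded shuffle.
#'
#' @param urls Character vector of URLs, or a tibble with a `url` column.
#' @param strata Stratum label per URL (defaults to the URL's ccTLD).
#' @param target_count Number of URLs withheld as targets.
#' @param seed Integer seed.
#' @return A list with tibbles `seeds` and `targets` (columns `url`,
#'   `stratum`); disjoint, jointly exhaustive.
#' @export
stratified_split <- function(urls, target_count, strata = NULL, seed = 1L) {
  if (is.data.frame(urls)) urls <- urls$url
  n <- length(urls)
  check_count(target_count, "target_count")
  if (target_count >= n) {
    stop_input("target_count must be smaller than the number of URLs")
  }
  if (is.null(strata)) {
    host <- sub("^https?://([^/:?#]+).*$", "\\1", urls)
    strata <- host_cctld(host)
  }
  tab <- table(strata)
  alloc <- largest_remainder(target_count, as.numeric(tab))
  names(alloc) <- names(tab)
  with_rng(seed, {
    target_idx <- unlist(lapply(names(tab), function(s) {
      idx <- which(strata == s)
      idx[sample.int(length(idx), alloc[[s]])]
    }), use.names = FALSE)
    tibble_of <- function(idx) {
      tibble::tibble(url = urls[idx], stratum = strata[idx])
    }
    list(seeds = tibble_of(setdiff(seq_len(n), target_idx)),
         targets = tibble_of(sort(target_idx)))
  })
}

#' Seed-target recall estimate
#'
#' `|S intersect T| / |T|` over normalized URLs: the fraction of withheld
#' target pages rediscovered by the crawl. This estimates the recall of the
#' crawl with respect to the (unknowable) relevant set only under the
#' assumption that the targets are a representative, unbiased sample of the
#' relevant pages, drawn independently of the crawling process.
#'
#' @param crawled Character vector of crawled URLs (the set S).
#' @param targets Character vector of target URLs (the set T); must be
#'   nonempty.
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' estimate_recall(c("http://a.de/", "http://b.de/"), c("http://b.de/"))
estimate_recall <- function(crawled, targets) {
  if (length(targets) == 0) stop_input("target set T must be nonempty")
  norm <- function(u) {
    n <- normalize_url(u)
    unique(n$url[n$ok])
  }
  s <- norm(crawled)
  t <- norm(targets)
  length(intersect(s, t)) / length(t)
}

rating_matrix <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0) || any(m != floor(m))) {
    stop_input("rating matrix must hold nonnegative integer counts")
  }
  m
}

#' Pairwise percent agreement over a rating matrix
#'
#' For each item (row of category counts), the fraction of agreeing rater
#' pairs among all rater pairs; the statistic is the unweighted mean over
#' items. Items with fewer than two ratings are excluded with a warning.
#'
#' @param m Items x categories matrix of rating counts.
#' @return A fraction in `[0, 1]`.
#' @export
percent_agreement <- function(m) {
  m <- rating_matrix(m)
  r <- rowSums(m)
  if (any(r < 2)) {
    warning(sum(r < 2), " item(s) with fewer than 2 ratings excluded")
    m <- m[r >= 2, , drop = FALSE]
    r <- r[r >= 2]
  }
  if (nrow(m) == 0) stop_input("no item with at least 2 ratings")
  agree <- rowSums(m * (m - 1)) / (r * (r - 1))
  mean(agree)
}

#' Fleiss' kappa
#'
#' Chance-corrected agreement for a fixed number of raters `r` per item:
#' `kappa = (Pbar - Pe) / (1 - Pe)` with per-item agreement
#' `P_i = (sum_j n_ij^2 - r) / (r (r - 1))` and chance agreement
#' `Pe = sum_j p_j^2`, `p_j` the overall share of category `j`.
#'
#' @param m Items x categories matrix of rating counts; all row sums must be
#'   equal and at least 2.
#' @return The kappa value (`<= 1`); errors if every rating falls in one
#'   category (`Pe = 1`, kappa undefined).
#' @export
fleiss_kappa <- function(m) {
  m <- rating_matrix(m)
  r <- unique(rowSums(m))
  if (length(r) != 1 || r < 2) {
    stop_input("Fleiss' kappa needs a constant rater count >= 2 per item")
  }
  n <- nrow(m)
  p_i <- (rowSums(m^2) - r) / (r * (r - 1))
  p_j <- colSums(m) / (n * r)
  p_bar <- mean(p_i)
  p_e <- sum(p_j^2)
  if (abs(1 - p_e) < 1e-12) {
    stop_input("kappa undefined: all ratings fall in a single category")
  }
  (p_bar - p_e) / (1 - p_e)
}

#' Read a ratings CSV (item_id, one count column per category)
#' @param path CSV path.
#' @return Numeric matrix with item ids as row names.
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
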