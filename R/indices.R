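#' Target preference index
#'
#' Difference in time spent courting each of two simultaneously presented
#' targets normalized by the sum: `(t1 - t2) / (t1 + t2)`, in `[-1, 1]`.
#' Undefined (and flagged for exclusion from group statistics) when no
#' courtship occurred toward either target.
#'
#' @param t1,t2 Nonnegative times (seconds) spent courting target 1 and 2.
#'   Vectorized.
#' @return Tibble with `index`, `t1`, `t2`, `defined`.
#' @examples
#' preference_index(30, 10)  # 0.5
#' @export
preference_index <- function(t1, t2) {
  if (any(t1 < 0) || any(t2 < 0)) stop("times must be nonnegative")
  tot <- t1 + t2
  tibble::tibble(index = ifelse(tot > 0, (t1 - t2) / tot, NA_real_),
                 t1 = t1, t2 = t2, defined = tot > 0)
}

#' Dominance (one-sidedness) of a behavior within a pair
#'
#' Asymmetry of a behavior's total duration between the two members of a
#' dyad: `|tA - tB| / (tA + tB)` in `[0, 1]`, with the dominant fly being
#' the one with the larger time. A tie (including 0, 0) leaves the
#' dominant undefined with bias 0 (or `NA` when neither fly performed the
#' behavior).
#'
#' @param tA,tB Nonnegative behavior times (seconds) for the two flies.
#' @param fly_ids Length-2 identifiers, default `c("A", "B")`.
#' @return Tibble with `bias`, `dominant`, `tA`, `tB`, `defined`.
#' @export
dominance <- function(tA, tB, fly_ids = c("A", "B")) {
  stopifnot(tA >= 0, tB >= 0, length(fly_ids) == 2)
  tot <- tA + tB
  if (tot == 0) {
    return(tibble::tibble(bias = NA_real_, dominant = NA_character_,
                          tA = tA, tB = tB, defined = FALSE))
  }
  dom <- if (tA > tB) fly_ids[1] else if (tB > tA) fly_ids[2]
         else NA_character_
  tibble::tibble(bias = abs(tA - tB) / tot, dominant = dom,
                 tA = tA, tB = tB, defined = TRUE)
}

#' Concordance of attack and courtship dominance across pairs
#'
#' Fraction of pairs in which the same fly is dominant for both actions
#' (e.g. high attack bias where the same fly also showed a majority of
#' courtship), with an exact binomial test against random chance (50%).
#' Pairs where either action's dominant is undefined are excluded.
#'
#' @param pairs Tibble with columns `pair_id`, `attack_dominant`,
#'   `courtship_dominant` (fly ids; `NA` = undefined).
#' @return Tibble with `n`, `concordant`, `fraction`, `p_value` (two-sided
#'   exact binomial vs 0.5).
#' @export
action_concordance <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  ok <- !is.na(pairs$attack_dominant) & !is.na(pairs$courtship_dominant)
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no pairs with both actions defined")
  conc <- sum(pairs$attack_dominant == pairs$courtship_dominant)
  n <- nrow(pairs)
  p <- stats::binom.test(conc, n, p = 0.5)$p.value
  tibble::tibble(n = n, concordant = conc, fraction = conc / n, p_value = p)
}

#' Sexual priming concordance between pair and trio phases
#'
#' Two males interact alone (pair phase), then a female is added (trio
#' phase). For each pair, male-directed courtship dominance in the pair
#' phase is compared with female-directed courtship dominance in the trio:
#' x is the pair-phase dominance signed toward the pair-dominant fly
#' (hence nonnegative), y is that same fly's signed trio-phase dominance,
#' and the dot size is the total pair-phase courtship. Pairs with less
#' than `min_pair_courtship` seconds of male-directed courtship are
#' filtered out. A trio is concordant when y > 0 (ties count as
#' non-concordant).
#'
#' @param data Tibble with two rows per pair: columns `pair_id`, `fly_id`,
#'   `pair_time_s` (male-directed courtship in the pair phase) and
#'   `trio_time_s` (female-directed courtship in the trio phase).
#' @param min_pair_courtship Minimum total pair-phase courtship (s) for a
#'   pair to be scored (default 20).
#' @param high_bias Threshold above which a pair counts as "high
#'   dominance" (default 0.8), reported separately.
#' @return List with `rows` (tibble `pair_id`, `dominant_fly`, `x`, `y`,
#'   `total_pair_s`, `concordant`, `high_bias`) and `summary` (tibble
#'   `n`, `concordant`, `fraction`, `p_value`, `n_high`,
#'   `concordant_high`).
#' @export
priming_concordance <- function(data, min_pair_courtship = 20,
                                high_bias = 0.8) {
  data <- tibble::as_tibble(data)
  need <- c("pair_id", "fly_id", "pair_time_s", "trio_time_s")
  stopifnot(all(need %in% names(data)))
  rows <- data |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) != 2) stop("each pair needs exactly two flies")
      tot <- sum(d$pair_time_s)
      if (tot < min_pair_courtship || tot == 0) return(tibble::tibble())
      i <- which.max(d$pair_time_s)   # pair-dominant fly (ties -> first)
      j <- 3 - i
      x <- (d$pair_time_s[i] - d$pair_time_s[j]) / tot
      trio_tot <- sum(d$trio_time_s)
      y <- if (trio_tot > 0) {
        (d$trio_time_s[i] - d$trio_time_s[j]) / trio_tot
      } else 0
      tibble::tibble(dominant_fly = d$fly_id[i], x = x, y = y,
                     total_pair_s = tot, concordant = y > 0,
                     high_bias = x >= high_bias)
    }) |>
    dplyr::ungroup()
  if (nrow(rows) == 0) stop("no pairs pass the courtship filter")
  n <- nrow(rows)
  conc <- sum(rows$concordant)
  summary <- tibble::tibble(
    n = n, concordant = conc, fraction = conc / n,
    p_value = stats::binom.test(conc, n, 0.5)$p.value,
    n_high = sum(rows$high_bias),
    concordant_high = sum(rows$concordant & rows$high_bias))
  list(rows = rows, summary = summary)
}

#' Normalized ovipositor extrusion
#'
#' Female rejection relative to male courtship drive: the difference
#' divided by the sum of time the female spent in ovipositor extrusion
#' (OE) and time her partner spent in unilateral wing extension (UWE).
#' Ranges over `[-1, 1]`; 1 means rejection without courtship, -1
#' courtship without rejection. Undefined when both are zero.
#'
#' @param t_oe Female OE time (s). Vectorized.
#' @param t_uwe Partner male UWE time (s).
#' @return Numeric vector in `[-1, 1]` (`NA` where undefined).
#' @export
oe_normalized <- function(t_oe, t_uwe) {
  if (any(t_oe < 0) || any(t_uwe < 0)) stop("times must be nonnegative")
  tot <- t_oe + t_uwe
  ifelse(tot > 0, (t_oe - t_uwe) / tot, NA_real_)
}

#' Group receptivity index
#'
#' Each female's acceptance (wing spreading, WS) and rejection (OE) are
#' binarized — WS present when `t_WS > 0`, OE present when the normalized
#' OE exceeds -0.25, both strictly — and her contribution is the
#' difference `WS - OE`, so 1, 0 or -1. The group index is the mean
#' contribution over scored females. A female with no WS and an undefined
#' normalized OE (neither OE nor partner UWE observed) is unscorable and
#' excluded; if every female is unscorable the group index is undefined.
#'
#' @param females Tibble with columns `t_ws`, `t_oe`, `t_uwe` (that
#'   female's wing spreading and OE times and her partner's UWE time, s).
#' @param oe_threshold Strict threshold on normalized OE for "OE present"
#'   (default -0.25).
#' @return List with `per_female` (tibble adding `oe_norm`, `ws_present`,
#'   `oe_present`, `contribution`, `scored`) and `index` (group mean, `NA`
#'   when no female scored).
#' @export
receptivity_index <- function(females, oe_threshold = -0.25) {
  females <- tibble::as_tibble(females)
  stopifnot(all(c("t_ws", "t_oe", "t_uwe") %in% names(females)),
            nrow(females) >= 1)
  oe_norm <- oe_normalized(females$t_oe, females$t_uwe)
  ws_present <- females$t_ws > 0
  oe_present <- !is.na(oe_norm) & oe_norm > oe_threshold
  scored <- ws_present | !is.na(oe_norm)
  contribution <- ifelse(scored, as.integer(ws_present) -
                           as.integer(oe_present), NA_integer_)
  per_female <- dplyr::mutate(females, oe_norm = oe_norm,
                              ws_present = ws_present,
                              oe_present = oe_present,
                              contribution = contribution, scored = scored)
  idx <- if (any(scored)) mean(contribution[scored]) else NA_real_
  list(per_female = per_female, index = idx)
}
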