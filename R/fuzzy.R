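# Fuzzy gain scheduling: maps the normalized muscle stiffness Ka and its
# change rate dKa to the controller stiffness parameter Kd-tilde through
# a 5x5 rule base over triangular membership partitions.

FUZZY_LABELS <- c("VS", "SL", "ME", "RL", "LE")

#' Triangular fuzzy partition
#'
#' Five symmetric triangular membership functions with 50% overlap and
#' equally spaced peaks spanning the universe. The outer sets (VS, LE)
#' saturate beyond their peaks, so extreme inputs fire fully. The
#' partition sums to 1 everywhere (at most two labels are active at any
#' point).
#'
#' @param lo,hi universe bounds, `lo < hi`.
#' @return list of class `fuzzy_partition` with `lo`, `hi`, `labels`,
#'   `peaks`.
#' @export
fuzzy_partition <- function(lo = 0, hi = 1) {
  if (!(lo < hi)) stop("universe must satisfy lo < hi", call. = FALSE)
  structure(list(lo = lo, hi = hi, labels = FUZZY_LABELS,
                 peaks = seq(lo, hi, length.out = 5)),
            class = "fuzzy_partition")
}

#' Membership degrees of a crisp value
#'
#' @param x crisp input; values outside the universe are clamped to it.
#' @param partition a [fuzzy_partition()].
#' @return named numeric vector of degrees, one per label, summing to 1.
#' @export
fuzzy_membership <- function(x, partition) {
  stopifnot(inherits(partition, "fuzzy_partition"))
  x <- clamp(x, partition$lo, partition$hi)
  h <- (partition$hi - partition$lo) / 4
  deg <- pmax(1 - abs(x - partition$peaks) / h, 0)
  deg[1] <- if (x <= partition$peaks[1]) 1 else deg[1]
  deg[5] <- if (x >= partition$peaks[5]) 1 else deg[5]
  names(deg) <- partition$labels
  deg
}

# Centroid (center of area) of one consequent set over its universe;
# interior triangles centre on their peak, shoulder sets sit one third
# of a partition step inside the universe end.
consequent_centroids <- function(partition) {
  h <- (partition$hi - partition$lo) / 4
  c(partition$lo + h / 3, partition$peaks[2:4], partition$hi - h / 3)
}

#' The compliant-controller rule base
#'
#' Returns the 25-rule table mapping `(Ka, dKa)` linguistic levels to
#' the controller-stiffness level: high muscle stiffness and fast
#' stiffness rise call for a large controller stiffness (quick, firm
#' grasp); low values call for a small one (slow, gentle grasp). The
#' consequents are non-decreasing along both inputs.
#'
#' @return 5x5 character matrix of class `fuzzy_rulebase`; rows are `Ka`
#'   labels (VS..LE ascending), columns are `dKa` labels.
#' @export
build_rulebase <- function() {
  tab <- rbind(
    VS = c("VS", "VS", "SL", "ME", "RL"),
    SL = c("VS", "VS", "ME", "ME", "RL"),
    ME = c("SL", "SL", "ME", "RL", "LE"),
    RL = c("SL", "ME", "ME", "RL", "LE"),
    LE = c("SL", "ME", "RL", "LE", "LE"))
  colnames(tab) <- FUZZY_LABELS
  structure(tab, class = c("fuzzy_rulebase", class(tab)))
}

validate_rulebase <- function(rules) {
  if (!all(dim(rules) == c(5, 5)) || !all(rules %in% FUZZY_LABELS))
    stop("rule base must be a 5x5 table of VS/SL/ME/RL/LE labels", call. = FALSE)
  invisible(rules)
}

#' Fuzzy inference of the controller stiffness
#'
#' Fires all 25 rules on `(Ka, dKa)` and defuzzifies to a crisp
#' controller stiffness on the output universe.
#'
#' Two inference schemes are available. The default,
#' `"center-average"`, uses product rule firing and the weighted mean
#' of the consequent-set centroids; with the partition-of-unity inputs
#' this is exactly bilinear interpolation of the rule table and is
#' therefore monotone non-decreasing in both inputs. The classical
#' `"centroid"` scheme (min firing, max aggregation, center-of-area
#' defuzzification) is kept for comparison; it is not exactly monotone
#' for this rule table.
#'
#' @param Ka normalized muscle stiffness in `[0, 1]` (clamped to the
#'   input universe).
#' @param dKa normalized stiffness change rate in `[0, 1]` (clamped to
#'   the input universe).
#' @param rules a [build_rulebase()] table.
#' @param out_partition output universe partition; default `[0, 100]`.
#' @param ka_partition,dka_partition input universe partitions. The
#'   defaults (`[0, 0.08]` for `Ka`, `[0, 0.05]` for `dKa`) span the
#'   range the estimates take over everyday grasp efforts (soft cup to
#'   rigid cup), so the rule base discriminates between such grasps;
#'   values beyond a universe saturate its LE set.
#' @param method `"center-average"` (default) or `"centroid"`.
#' @return crisp controller stiffness within the output universe.
#' @examples
#' infer_kd(0.8, 0.6)
#' @export
infer_kd <- function(Ka, dKa, rules = build_rulebase(),
                     out_partition = fuzzy_partition(0, 100),
                     ka_partition = fuzzy_partition(0, 0.08),
                     dka_partition = fuzzy_partition(0, 0.05),
                     method = c("center-average", "centroid")) {
  method <- match.arg(method)
  validate_rulebase(rules)
  mka <- fuzzy_membership(Ka, ka_partition)
  mdk <- fuzzy_membership(dKa, dka_partition)
  idx <- matrix(match(rules, FUZZY_LABELS), 5, 5)
  if (method == "center-average") {
    w <- outer(mka, mdk)           # product firing, sums to 1
    cents <- consequent_centroids(out_partition)
    return(sum(w * cents[idx]) / sum(w))
  }
  # classical Mamdani: min firing, max aggregation, centroid defuzz
  z <- seq(out_partition$lo, out_partition$hi, length.out = 1001)
  mu_out <- vapply(z, function(zz) fuzzy_membership(zz, out_partition),
                   numeric(5))
  agg <- numeric(length(z))
  for (i in 1:5) for (j in 1:5) {
    wij <- min(mka[i], mdk[j])
    if (wij > 0) agg <- pmax(agg, pmin(wij, mu_out[idx[i, j], ]))
  }
  if (sum(agg) <= 0)
    stop("degenerate aggregate in fuzzy inference", call. = FALSE)
  sum(z * agg) / sum(agg)
}

#' Export / import a rule base as plain text
#'
#' Writes the 5x5 consequent grid (rows = `Ka` ascending, columns =
#' `dKa` ascending) as whitespace-separated text, and reads it back.
#'
#' @param rules a `fuzzy_rulebase`.
#' @param path file path.
#' @export
write_rulebase <- function(rules, path) {
  validate_rulebase(rules)
  writeLines(apply(rules, 1, paste, collapse = " "), path)
  invisible(path)
}

#' @rdname write_rulebase
#' @export
read_rulebase <- function(path) {
  rows <- strsplit(trimws(readLines(path)), "\\s+")
  tab <- do.call(rbind, rows)
  dimnames(tab) <- list(FUZZY_LABELS, FUZZY_LABELS)
  validate_rulebase(tab)
  structure(tab, class = c("fuzzy_rulebase", class(tab)))
}
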