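#' Data editing rules
#'
#' The standard pre-analysis edits for field weight records: trim outliers
#' beyond `sd_trim` standard deviations from the overall trait mean, then
#' drop contemporary groups below `min_cg_size` records and sire families
#' below `min_sire_progeny` progeny, iterating the last two rules to a fixed
#' point (dropping a small CG can shrink a sire family below its threshold
#' and vice versa).
#'
#' @param sd_trim outlier trim multiplier (mean +/- sd_trim * SD).
#' @param min_cg_size minimum records per contemporary group.
#' @param min_sire_progeny minimum progeny per retained sire.
#' @return list of class `"edit_rules"`.
#' @export
edit_rules <- function(sd_trim = 3.5, min_cg_size = 25,
                       min_sire_progeny = 50) {
  stopifnot(sd_trim > 0, min_cg_size > 0, min_sire_progeny > 0)
  structure(list(sd_trim = sd_trim, min_cg_size = as.integer(min_cg_size),
                 min_sire_progeny = as.integer(min_sire_progeny)),
            class = "edit_rules")
}

#' Apply data editing rules
#'
#' @param data data.frame with at least columns `y`, `cg` and `sire`
#'   (`NA` = unknown sire; unknown-sire records are exempt from the
#'   sire-family rule but still subject to the others).
#' @param rules an [edit_rules()] object.
#' @return the retained records, with an attribute `removal_log`: a named
#'   integer vector of records removed per rule.
#' @export
apply_edit_rules <- function(data, rules = edit_rules()) {
  stopifnot(inherits(rules, "edit_rules"),
            all(c("y", "cg", "sire") %in% names(data)))
  log <- c(sd_trim = 0L, min_cg_size = 0L, min_sire_progeny = 0L)

  mu <- mean(data$y)
  s <- stats::sd(data$y)
  keep <- abs(data$y - mu) <= rules$sd_trim * s
  log["sd_trim"] <- sum(!keep)
  data <- data[keep, , drop = FALSE]

  repeat {
    n_cg <- table(data$cg)
    drop_cg <- data$cg %in% names(n_cg)[n_cg < rules$min_cg_size]
    log["min_cg_size"] <- log["min_cg_size"] + sum(drop_cg)
    data <- data[!drop_cg, , drop = FALSE]

    n_s <- table(data$sire[!is.na(data$sire)])
    drop_s <- !is.na(data$sire) &
      data$sire %in% names(n_s)[n_s < rules$min_sire_progeny]
    log["min_sire_progeny"] <- log["min_sire_progeny"] + sum(drop_s)
    data <- data[!drop_s, , drop = FALSE]

    if (sum(drop_cg) == 0L && sum(drop_s) == 0L) break
  }
  if (nrow(data) == 0L) stop("no records survive editing")
  attr(data, "removal_log") <- log
  data
}
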