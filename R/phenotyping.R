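# Starvation-induced hyperactivity (SIH) phenotyping: window-wise Delta
# Activity, per-fly maximum DA, strain summaries, baseline activity, and the
# activity-inferred starvation-resistance index.

WINDOWS <- list(N1 = 0:23, D1 = 24:47, N2 = 48:71, D2 = 72:95, N3 = 96:119)

#' Per-fly 12-hour window totals
#'
#' Sums each fly's beam-break counts over the five consecutive 12-h windows
#' of the 60-h assay (three nights, two days): N1 = bins 0-23, D1 = 24-47,
#' N2 = 48-71, D2 = 72-95, N3 = 96-119. A window is only reported when all
#' 24 of its bins are present; incomplete windows are `NA` (with a warning),
#' and flies with no complete window are dropped.
#'
#' @param activity Long-format activity data frame (see
#'   [to_activity_table()]).
#' @return Data frame with `fly_id`, `strain_id`, `condition` and one column
#'   per window (`N1`, `D1`, `N2`, `D2`, `N3`).
#' @export
window_sums <- function(activity) {
  if (nrow(activity) == 0L) {
    return(data.frame(fly_id = character(0), strain_id = character(0),
                      condition = character(0), N1 = numeric(0),
                      D1 = numeric(0), N2 = numeric(0), D2 = numeric(0),
                      N3 = numeric(0)))
  }
  flies <- unique(activity[, c("fly_id", "strain_id", "condition")])
  sums <- matrix(NA_real_, nrow = nrow(flies), ncol = 5,
                 dimnames = list(NULL, names(WINDOWS)))
  split_idx <- split(seq_len(nrow(activity)), activity$fly_id)
  incomplete <- 0L
  for (i in seq_len(nrow(flies))) {
    idx <- split_idx[[flies$fly_id[i]]]
    bins <- activity$bin_index[idx]
    cnts <- activity$count[idx]
    for (w in seq_along(WINDOWS)) {
      wb <- WINDOWS[[w]]
      sel <- bins %in% wb
      if (sum(sel) == 24L) {
        sums[i, w] <- sum(cnts[sel])
      } else {
        incomplete <- incomplete + 1L
      }
    }
  }
  keep <- rowSums(!is.na(sums)) > 0L
  if (incomplete > 0L) {
    warning(sprintf("%d incomplete fly-windows excluded", incomplete))
  }
  if (any(!keep)) {
    warning(sprintf("%d flies with no complete window dropped", sum(!keep)))
  }
  out <- cbind(flies[keep, , drop = FALSE],
               as.data.frame(sums[keep, , drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Per-strain food-condition window baseline
#'
#' @param ws Window-sum data frame from [window_sums()]; only rows with
#'   `condition == "food"` are used.
#' @return Data frame with `strain_id` and the mean food-condition total for
#'   each of the five windows.
#' @export
food_baseline <- function(ws) {
  food <- ws[ws$condition == "food", , drop = FALSE]
  if (nrow(food) == 0L) stop("no food-condition flies for baseline")
  agg <- stats::aggregate(food[, names(WINDOWS)],
                          by = list(strain_id = food$strain_id),
                          FUN = mean, na.rm = TRUE)
  agg
}

#' Per-fly Delta Activity
#'
#' For each starved fly, the Delta Activity in window w is the fly's window
#' total minus the strain-mean food-condition total for that window; the
#' fly's DA is the largest (signed maximum) of its five window DAs. Flies
#' whose strain lacks a baseline for some window with data are excluded.
#'
#' @param ws Window sums from [window_sums()] (both conditions), or only the
#'   starved rows if `baseline` is supplied.
#' @param baseline Optional per-strain window baseline from
#'   [food_baseline()]; computed from `ws` when missing.
#' @return Data frame with `fly_id`, `strain_id`, `da_N1` .. `da_N3` and
#'   `da` (the per-fly maximum).
#' @export
delta_activity <- function(ws, baseline = NULL) {
  if (is.null(baseline)) baseline <- food_baseline(ws)
  starved <- ws[ws$condition == "starvation", , drop = FALSE]
  m <- match(starved$strain_id, baseline$strain_id)
  ok <- !is.na(m)
  if (any(!ok)) {
    warning(sprintf("%d starved flies without strain baseline excluded",
                    sum(!ok)))
  }
  starved <- starved[ok, , drop = FALSE]
  m <- m[ok]
  da_w <- as.matrix(starved[, names(WINDOWS)]) -
    as.matrix(baseline[m, names(WINDOWS)])
  complete <- rowSums(is.na(da_w)) == 0L
  if (any(!complete)) {
    warning(sprintf("%d starved flies with undefined window DA excluded",
                    sum(!complete)))
  }
  da_w <- da_w[complete, , drop = FALSE]
  starved <- starved[complete, , drop = FALSE]
  out <- data.frame(fly_id = starved$fly_id, strain_id = starved$strain_id,
                    stringsAsFactors = FALSE)
  colnames(da_w) <- paste0("da_", names(WINDOWS))
  out <- cbind(out, as.data.frame(da_w))
  out$da <- if (nrow(da_w)) apply(da_w, 1, max) else numeric(0)
  rownames(out) <- NULL
  out
}

#' Strain-level SIH summary
#'
#' Mean and SEM of per-fly DA for each strain, together with the strain
#' baseline activity (strain mean of food-condition flies' total counts over
#' the whole assay). With a single starved fly the SEM is `NA`.
#'
#' @param fly_das Per-fly DA table from [delta_activity()].
#' @param activity Activity table (for the food-condition baseline).
#' @return Data frame with `strain_id`, `da_mean`, `da_sem`, `n_flies`,
#'   `baseline`.
#' @export
strain_summary <- function(fly_das, activity) {
  sp <- split(fly_das$da, fly_das$strain_id)
  res <- data.frame(strain_id = names(sp),
                    da_mean = vapply(sp, mean, 0),
                    da_sem = vapply(sp, function(v)
                      if (length(v) >= 2) stats::sd(v) / sqrt(length(v))
                      else NA_real_, 0),
                    n_flies = vapply(sp, length, 0L),
                    stringsAsFactors = FALSE)
  food <- activity[activity$condition == "food", , drop = FALSE]
  if (nrow(food)) {
    per_fly <- stats::aggregate(count ~ fly_id + strain_id, data = food,
                                FUN = sum)
    per_strain <- stats::aggregate(count ~ strain_id, data = per_fly,
                                   FUN = mean)
    res$baseline <- per_strain$count[match(res$strain_id,
                                           per_strain$strain_id)]
  } else {
    res$baseline <- NA_real_
  }
  rownames(res) <- NULL
  res
}

#' Starvation-resistance index from activity-inferred death
#'
#' A starved fly's death bin is one past its last bin with any beam cross
#' (0 for an all-zero record); a fly still crossing the beam in the final
#' bin is a survivor. The strain's SR index is the largest death bin among
#' its starved flies, or 121 when any fly survives the whole assay.
#'
#' @param activity Activity table; only `condition == "starvation"` rows are
#'   used.
#' @param last_bin Index of the final assay bin (default 119).
#' @return Data frame with `strain_id` and integer `sr`.
#' @export
starvation_resistance <- function(activity, last_bin = 119L) {
  starved <- activity[activity$condition == "starvation", , drop = FALSE]
  if (nrow(starved) == 0L) stop("no starved flies")
  key <- paste(starved$fly_id, starved$strain_id, sep = "\r")
  per_fly <- split(starved[, c("bin_index", "count")], key, drop = TRUE)
  fly_strain <- sub(".*\r", "", names(per_fly))
  death_bin <- numeric(length(per_fly))
  survivor <- logical(length(per_fly))
  for (i in seq_along(per_fly)) {
    d <- per_fly[[i]]
    nz <- d$bin_index[d$count > 0]
    if (length(nz) == 0L) {
      death_bin[i] <- 0
    } else if (max(nz) >= last_bin) {
      survivor[i] <- TRUE
    } else {
      death_bin[i] <- max(nz) + 1L
    }
  }
  sp <- split(seq_along(per_fly), fly_strain)
  data.frame(strain_id = names(sp),
             sr = vapply(sp, function(idx)
               if (any(survivor[idx])) 121L
               else as.integer(max(death_bin[idx])), 0L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full strain phenotype table
#'
#' Convenience wrapper running [window_sums()], [delta_activity()],
#' [strain_summary()] and [starvation_resistance()] and joining the results
#' into an S1-style strain phenotype table.
#'
#' @param activity Activity table with both conditions.
#' @return Data frame with `strain_id`, `da_mean`, `da_sem`, `sr`,
#'   `baseline`, `n_flies`.
#' @export
strain_phenotypes <- function(activity) {
  ws <- window_sums(activity)
  das <- delta_activity(ws)
  summ <- strain_summary(das, activity)
  sr <- starvation_resistance(activity)
  summ$sr <- sr$sr[match(summ$strain_id, sr$strain_id)]
  summ[, c("strain_id", "da_mean", "da_sem", "sr", "baseline", "n_flies")]
}
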