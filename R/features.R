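# Motion-analysis features (MAFs).
#
# 280 features in four categories: 5 trial-time, 8 tip-visibility, 20 grip,
# and 247 tip-motion. Table-driven: maf_manifest() is the normative, ordered
# enumeration (version-locked), and extract_mafs() computes values in
# exactly that order. Sensor-subset models (T/TG/TM/TMV/TMG/TMVG) restrict
# to category subsets.

MANIFEST_VERSION <- "1.0"

# peak-count thresholds, as printed in the feature table
PEAK_THRESHOLDS <- list(
  ivel_lin = c(2, 5, 10, 100),      # cm/s
  ivel_ang = c(1, 10, 20, 200),     # deg/s
  iacc_lin = c(10, 100, 1000, 10000),   # cm/s^2
  iacc_ang = c(50, 100, 1000, 10000),   # deg/s^2
  grip_vel = c(5, 10, 20),          # deg/s
  grip_acc = 100                    # deg/s^2
)

# |v| <= eps counts as "zero" on noisy derivative signals
GRIP_EPS_VEL <- 1    # deg/s
GRIP_EPS_ACC <- 10   # deg/s^2

#' Map a sensor-subset code to MAF categories
#'
#' @param subset one of "T", "TG", "TM", "TMV", "TMG", "TMVG".
#' @return character vector of categories (time, grip, tip_motion,
#'   visibility).
#' @export
subset_categories <- function(subset) {
  subset <- match.arg(subset, c("T", "TG", "TM", "TMV", "TMG", "TMVG"))
  map <- c(T = "time", G = "grip", M = "tip_motion", V = "visibility")
  unname(map[strsplit(subset, "")[[1]]])
}

#' The normative ordered manifest of all 280 motion-analysis features
#'
#' Category counts are fixed at 5 (time), 8 (visibility), 20 (grip) and 247
#' (tip motion); ratio features are needle/maryland. The ordering is
#' version-locked (`attr(,"version")`): models and feature files refer to
#' features by these names.
#'
#' @return data.frame with columns `name`, `category`, `subcategory`,
#'   `tool`, `units`; 280 rows.
#' @export
maf_manifest <- function() {
  rows <- list()
  add <- function(name, category, subcategory, tool, units)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, category = category, subcategory = subcategory,
      tool = tool, units = units)

  # -- time (5): T, T^2, sqrt(T), 1/T, 1/T^2
  add("trial_time", "time", "duration", "none", "s")
  add("trial_time_sq", "time", "duration", "none", "s^2")
  add("trial_time_sqrt", "time", "duration", "none", "s^0.5")
  add("trial_time_inv", "time", "duration", "none", "1/s")
  add("trial_time_inv_sq", "time", "duration", "none", "1/s^2")

  # -- visibility (8): per tool time in/out of view and their fractions
  for (tool in TOOLS) {
    add(paste0("vis_time_in_", tool), "visibility", "time", tool, "s")
    add(paste0("vis_time_out_", tool), "visibility", "time", tool, "s")
    add(paste0("vis_frac_in_", tool), "visibility", "fraction", tool, "1")
    add(paste0("vis_frac_out_", tool), "visibility", "fraction", tool, "1")
  }

  # -- grip (20): per tool velocity peaks/dwell and acceleration peaks/dwell
  for (tool in TOOLS) {
    for (th in PEAK_THRESHOLDS$grip_vel)
      add(paste0("grip_vel_peakrate_", th, "_", tool), "grip", "velocity",
          tool, "peaks/s")
    add(paste0("grip_vel_time_zero_", tool), "grip", "velocity", tool, "s")
    add(paste0("grip_vel_time_moving_", tool), "grip", "velocity", tool, "s")
    add(paste0("grip_vel_zero_frac_", tool), "grip", "velocity", tool, "1")
    add(paste0("grip_acc_peakrate_", PEAK_THRESHOLDS$grip_acc, "_", tool),
        "grip", "acceleration", tool, "peaks/s")
    add(paste0("grip_acc_time_zero_", tool), "grip", "acceleration", tool, "s")
    add(paste0("grip_acc_time_moving_", tool), "grip", "acceleration", tool, "s")
    add(paste0("grip_acc_zero_frac_", tool), "grip", "acceleration", tool, "1")
  }

  # -- tip motion (247)
  # linear path (16)
  path_items <- c("x", "y", "z", "total", "bbox_diag")
  for (tool in TOOLS)
    for (it in path_items)
      add(paste0("path_", it, "_", tool), "tip_motion", "linear_path", tool, "cm")
  for (it in path_items)
    add(paste0("ratio_path_", it), "tip_motion", "linear_path", "both", "1")
  add("path_total_sum", "tip_motion", "linear_path", "both", "cm")

  # angular path (15)
  apath_items <- c("roll", "elev", "azim", "total", "range_sum")
  for (tool in TOOLS)
    for (it in apath_items)
      add(paste0("apath_", it, "_", tool), "tip_motion", "angular_path", tool, "deg")
  for (it in apath_items[1:4])
    add(paste0("ratio_apath_", it), "tip_motion", "angular_path", "both", "1")
  add("apath_total_sum", "tip_motion", "angular_path", "both", "deg")

  # average linear/angular speed and acceleration magnitudes (4 x 12)
  avg_specs <- list(
    avgspeed_lin = c("average_linear_speed", "cm/s"),
    avgspeed_ang = c("average_angular_speed", "deg/s"),
    avgacc_lin = c("average_linear_acceleration", "cm/s^2"),
    avgacc_ang = c("average_angular_acceleration", "deg/s^2"))
  for (pre in names(avg_specs)) {
    sc <- avg_specs[[pre]][1]; un <- avg_specs[[pre]][2]
    for (tool in TOOLS)
      for (ax in c("x", "y", "z", "mag"))
        add(paste0(pre, "_", ax, "_", tool), "tip_motion", sc, tool, un)
    for (ax in c("x", "y", "z", "mag"))
      add(paste0("ratio_", pre, "_", ax), "tip_motion", sc, "both", "1")
  }

  # instantaneous velocity/acceleration statistics and peak rates (4 x 42)
  inst_specs <- list(
    ivel_lin = c("instantaneous_linear_velocity", "cm/s"),
    ivel_ang = c("instantaneous_angular_velocity", "deg/s"),
    iacc_lin = c("instantaneous_linear_acceleration", "cm/s^2"),
    iacc_ang = c("instantaneous_angular_acceleration", "deg/s^2"))
  for (pre in names(inst_specs)) {
    sc <- inst_specs[[pre]][1]; un <- inst_specs[[pre]][2]
    for (tool in TOOLS) {
      for (ax in c("x", "y", "z"))
        for (st in c("max", "min", "range", "std"))
          add(paste0(pre, "_", ax, "_", st, "_", tool), "tip_motion", sc, tool, un)
      for (st in c("max", "std"))
        add(paste0(pre, "_mag_", st, "_", tool), "tip_motion", sc, tool, un)
    }
    for (ax in c("x", "y", "z"))
      add(paste0("ratio_", pre, "_", ax, "_std"), "tip_motion", sc, "both", "1")
    add(paste0("ratio_", pre, "_mag_max"), "tip_motion", sc, "both", "1")
    add(paste0("ratio_", pre, "_mag_std"), "tip_motion", sc, "both", "1")
    for (tool in TOOLS)
      for (th in PEAK_THRESHOLDS[[pre]])
        add(paste0(pre, "_peakrate_", th, "_", tool), "tip_motion", sc, tool,
            "peaks/s")
    add(paste0(pre, "_peaksum_", PEAK_THRESHOLDS[[pre]][1]), "tip_motion",
        sc, "both", "peaks/s")
  }

  out <- do.call(rbind, rows)
  stopifnot(nrow(out) == 280, !anyDuplicated(out$name),
            sum(out$category == "time") == 5,
            sum(out$category == "visibility") == 8,
            sum(out$category == "grip") == 20,
            sum(out$category == "tip_motion") == 247)
  attr(out, "version") <- MANIFEST_VERSION
  out
}

#' Count local maxima at or above a threshold
#'
#' A peak is an interior sample with s[i] > s[i-1], s[i] >= s[i+1] and
#' s[i] >= threshold; intended for nonnegative magnitude series. Series
#' shorter than 3 samples have no peaks.
#'
#' @param x numeric vector on a uniform grid.
#' @param threshold numeric scalar.
#' @return integer count.
#' @export
count_peaks <- function(x, threshold) {
  n <- length(x)
  if (n < 3) return(0L)
  i <- 2:(n - 1)
  sum(x[i] > x[i - 1] & x[i] >= x[i + 1] & x[i] >= threshold)
}

ratio_or_zero <- function(num, den) {
  ifelse(abs(den) < 1e-9, 0, num / den)
}

rownorm <- function(m) sqrt(rowSums(m^2))

#' Extract motion-analysis features from trial kinematics
#'
#' Computes the features named by [maf_manifest()], in manifest order,
#' optionally restricted to a category subset. Peak counts are divided by
#' trial time; tool ratios are needle/maryland with a zero result when the
#' denominator magnitude is below 1e-9 (keeps every value finite for
#' downstream standardization).
#'
#' @param kin a `trial_kinematics`.
#' @param categories categories to include (default: all four).
#' @return named numeric vector, a subset of the manifest in manifest order.
#' @export
extract_mafs <- function(kin, categories = c("time", "visibility", "grip",
                                             "tip_motion")) {
  T <- kin$duration
  if (T <= 0) stop("empty trial: zero duration")
  v <- c()
  put <- function(name, value) v[name] <<- value

  put("trial_time", T)
  put("trial_time_sq", T^2)
  put("trial_time_sqrt", sqrt(T))
  put("trial_time_inv", 1 / T)
  put("trial_time_inv_sq", 1 / T^2)

  for (tool in TOOLS) {
    frac_in <- mean(kin$tools[[tool]]$visible)
    put(paste0("vis_time_in_", tool), T * frac_in)
    put(paste0("vis_time_out_", tool), T * (1 - frac_in))
    put(paste0("vis_frac_in_", tool), frac_in)
    put(paste0("vis_frac_out_", tool), 1 - frac_in)
  }

  for (tool in TOOLS) {
    k <- kin$tools[[tool]]
    av <- abs(k$grip_vel); aa <- abs(k$grip_acc)
    for (th in PEAK_THRESHOLDS$grip_vel)
      put(paste0("grip_vel_peakrate_", th, "_", tool), count_peaks(av, th) / T)
    fz <- mean(av <= GRIP_EPS_VEL)
    put(paste0("grip_vel_time_zero_", tool), T * fz)
    put(paste0("grip_vel_time_moving_", tool), T * (1 - fz))
    put(paste0("grip_vel_zero_frac_", tool), fz)
    put(paste0("grip_acc_peakrate_", PEAK_THRESHOLDS$grip_acc, "_", tool),
        count_peaks(aa, PEAK_THRESHOLDS$grip_acc) / T)
    fza <- mean(aa <= GRIP_EPS_ACC)
    put(paste0("grip_acc_time_zero_", tool), T * fza)
    put(paste0("grip_acc_time_moving_", tool), T * (1 - fza))
    put(paste0("grip_acc_zero_frac_", tool), fza)
  }

  # tip motion
  for (tool in TOOLS) {
    k <- kin$tools[[tool]]
    dp <- apply(k$tip_pos, 2, diff)
    if (is.null(dim(dp))) dp <- matrix(dp, nrow = 1)
    put(paste0("path_x_", tool), sum(abs(dp[, 1])))
    put(paste0("path_y_", tool), sum(abs(dp[, 2])))
    put(paste0("path_z_", tool), sum(abs(dp[, 3])))
    put(paste0("path_total_", tool), sum(rownorm(dp)))
    put(paste0("path_bbox_diag_", tool),
        sqrt(sum(apply(k$tip_pos, 2, function(cc) diff(range(cc)))^2)))
    de <- apply(k$euler, 2, diff)
    if (is.null(dim(de))) de <- matrix(de, nrow = 1)
    colnames(de) <- colnames(k$euler)
    put(paste0("apath_roll_", tool), sum(abs(de[, "roll"])))
    put(paste0("apath_elev_", tool), sum(abs(de[, "elevation"])))
    put(paste0("apath_azim_", tool), sum(abs(de[, "azimuth"])))
    put(paste0("apath_total_", tool), sum(rownorm(de)))
    put(paste0("apath_range_sum_", tool),
        sum(apply(k$euler, 2, function(cc) diff(range(cc)))))
    sigs <- list(avgspeed_lin = k$lin_vel, avgspeed_ang = k$ang_vel,
                 avgacc_lin = k$lin_acc, avgacc_ang = k$ang_acc)
    for (pre in names(sigs)) {
      s <- sigs[[pre]]
      put(paste0(pre, "_x_", tool), mean(abs(s[, 1])))
      put(paste0(pre, "_y_", tool), mean(abs(s[, 2])))
      put(paste0(pre, "_z_", tool), mean(abs(s[, 3])))
      put(paste0(pre, "_mag_", tool), mean(rownorm(s)))
    }
    isigs <- list(ivel_lin = k$lin_vel, ivel_ang = k$ang_vel,
                  iacc_lin = k$lin_acc, iacc_ang = k$ang_acc)
    for (pre in names(isigs)) {
      s <- isigs[[pre]]
      for (j in 1:3) {
        ax <- c("x", "y", "z")[j]
        put(paste0(pre, "_", ax, "_max_", tool), max(s[, j]))
        put(paste0(pre, "_", ax, "_min_", tool), min(s[, j]))
        put(paste0(pre, "_", ax, "_range_", tool), diff(range(s[, j])))
        put(paste0(pre, "_", ax, "_std_", tool), stats::sd(s[, j]))
      }
      mag <- rownorm(s)
      put(paste0(pre, "_mag_max_", tool), max(mag))
      put(paste0(pre, "_mag_std_", tool), stats::sd(mag))
      for (th in PEAK_THRESHOLDS[[pre]])
        put(paste0(pre, "_peakrate_", th, "_", tool),
            count_peaks(mag, th) / T)
    }
  }
  # cross-tool ratios and sums
  r <- function(stem) ratio_or_zero(v[paste0(stem, "_needle")],
                                    v[paste0(stem, "_maryland")])
  for (it in c("x", "y", "z", "total", "bbox_diag"))
    put(paste0("ratio_path_", it), r(paste0("path_", it)))
  put("path_total_sum", v["path_total_maryland"] + v["path_total_needle"])
  for (it in c("roll", "elev", "azim", "total"))
    put(paste0("ratio_apath_", it), r(paste0("apath_", it)))
  put("apath_total_sum", v["apath_total_maryland"] + v["apath_total_needle"])
  for (pre in c("avgspeed_lin", "avgspeed_ang", "avgacc_lin", "avgacc_ang"))
    for (ax in c("x", "y", "z", "mag"))
      put(paste0("ratio_", pre, "_", ax), r(paste0(pre, "_", ax)))
  for (pre in c("ivel_lin", "ivel_ang", "iacc_lin", "iacc_ang")) {
    for (ax in c("x", "y", "z"))
      put(paste0("ratio_", pre, "_", ax, "_std"), r(paste0(pre, "_", ax, "_std")))
    put(paste0("ratio_", pre, "_mag_max"), r(paste0(pre, "_mag_max")))
    put(paste0("ratio_", pre, "_mag_std"), r(paste0(pre, "_mag_std")))
    th1 <- PEAK_THRESHOLDS[[pre]][1]
    put(paste0(pre, "_peaksum_", th1),
        v[paste0(pre, "_peakrate_", th1, "_maryland")] +
          v[paste0(pre, "_peakrate_", th1, "_needle")])
  }

  man <- maf_manifest()
  keep <- man$name[man$category %in% categories]
  out <- unname(v[keep])
  names(out) <- keep
  stopifnot(all(is.finite(out)))
  out
}

#' Extract features for a list of trials into a feature matrix
#'
#' @param kins named list of `trial_kinematics` (names = trial ids).
#' @param categories categories to include.
#' @return data.frame: one row per trial, `trial_id` column plus one column
#'   per feature.
#' @export
extract_maf_table <- function(kins, categories = c("time", "visibility",
                                                   "grip", "tip_motion")) {
  stopifnot(length(kins) > 0)
  rows <- lapply(kins, extract_mafs, categories = categories)
  m <- do.call(rbind, rows)
  ids <- if (!is.null(names(kins))) names(kins) else as.character(seq_along(kins))
  cbind(data.frame(trial_id = ids), as.data.frame(m), row.names = NULL)
}
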