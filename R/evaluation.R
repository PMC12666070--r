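#' Euler angles (z-y-x convention) of a rotation matrix, in degrees
#'
#' Decomposes `R = Rz(yaw) Ry(pitch) Rx(roll)`.
#'
#' @param R 3 x 3 rotation matrix.
#' @return named numeric vector `(yaw, pitch, roll)` in degrees.
#' @export
euler_zyx <- function(R) {
  pitch <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(pitch)) > 1e-9) {
    roll <- atan2(R[3, 2], R[3, 3])
    yaw <- atan2(R[2, 1], R[1, 1])
  } else {
    roll <- atan2(-R[2, 3], R[2, 2])  # gimbal lock: fold yaw into roll
    yaw <- 0
  }
  c(yaw = yaw, pitch = pitch, roll = roll) * 180 / pi
}

#' Mean absolute rotation error, degrees
#'
#' Mean over the three z-y-x Euler angles of the absolute difference between
#' predicted and ground-truth rotations, each difference wrapped to
#' `[-180, 180]` degrees. This anglewise convention matches the
#' partial-to-partial registration literature; see
#' [geodesic_rotation_error()] for the geodesic alternative.
#'
#' @param pred,gt `rigid_transform` objects.
#' @return MAE(R) in degrees.
#' @export
mae_rotation <- function(pred, gt) {
  d <- euler_zyx(pred$rotation) - euler_zyx(gt$rotation)
  d <- (d + 180) %% 360 - 180
  mean(abs(d))
}

#' Geodesic rotation error, degrees
#' @param pred,gt `rigid_transform` objects.
#' @return angle of the relative rotation, degrees.
#' @export
geodesic_rotation_error <- function(pred, gt) {
  rotation_angle(pred$rotation %*% t(gt$rotation))
}

#' Mean absolute translation error, mm
#'
#' Mean over the three components of the absolute difference between
#' predicted and ground-truth translations, converted from normalized units
#' to millimetres through the normalization map.
#'
#' @param pred,gt `rigid_transform` objects in the normalized frame.
#' @param norm_map the pair's `normalization_map`.
#' @return MAE(t) in mm.
#' @export
mae_translation <- function(pred, gt, norm_map) {
  mean(abs(pred$translation - gt$translation)) * norm_map$scale
}

#' Target registration error, mm
#'
#' Mean Euclidean distance between the predicted-transform image of the
#' source landmarks and the target landmarks, in millimetres. Landmarks are
#' drawn from cropped-out regions, so TRE at the ground-truth transform
#' measures exactly the residual non-rigid (deformation) component.
#'
#' @param landmarks_source,landmarks_target n x 3 matrices of paired
#'   landmarks in the normalized frame.
#' @param pred predicted `rigid_transform` (normalized frame).
#' @param norm_map the pair's `normalization_map`.
#' @return TRE in mm.
#' @export
target_registration_error <- function(landmarks_source, landmarks_target,
                                      pred, norm_map) {
  ls <- as_coord_matrix(landmarks_source, "landmarks_source")
  lt <- as_coord_matrix(landmarks_target, "landmarks_target")
  if (nrow(ls) != nrow(lt) || nrow(ls) < 1) stop("landmark counts must match and be >= 1")
  moved <- apply_rigid(ls, pred)
  mean(sqrt(rowSums((moved - lt)^2))) * norm_map$scale
}

#' Correspondence precision and recall
#'
#' A predicted pair is correct when the ground-truth map sends its target
#' index to exactly its predicted source index. Precision is
#' correct/predicted (reported as 0 with a flag when nothing is predicted);
#' recall is correct/|ground truth|.
#'
#' @param predicted a `correspondence_set`.
#' @param gt_map integer vector: for target point i, the ground-truth source
#'   index.
#' @return list with `precision`, `recall`, `n_correct`, `n_predicted`,
#'   `n_gt` and `flag`.
#' @export
match_precision_recall <- function(predicted, gt_map) {
  if (!length(gt_map)) stop("ground-truth correspondence map is empty")
  n_pred <- length(predicted)
  n_gt <- length(gt_map)
  if (n_pred == 0) {
    return(list(precision = 0, recall = 0, n_correct = 0L, n_predicted = 0L,
                n_gt = n_gt, flag = "no_predictions"))
  }
  correct <- sum(gt_map[predicted$target_idx] == predicted$source_idx,
                 na.rm = TRUE)
  list(precision = correct / n_pred, recall = correct / n_gt,
       n_correct = as.integer(correct), n_predicted = as.integer(n_pred),
       n_gt = as.integer(n_gt), flag = NA_character_)
}

#' Score one predicted transform against a pair's ground truth
#'
#' @param pair a `pair_record`.
#' @param pred predicted `rigid_transform` (normalized frame) or a
#'   `registration_result`.
#' @param method optional method label carried into the output.
#' @return one-row tibble with `tre`, `mae_r`, `mae_t`, `mae_r_geodesic`
#'   (mm / degrees) and bookkeeping columns.
#' @export
evaluate_pair <- function(pair, pred, method = NA_character_) {
  if (inherits(pred, "registration_result")) pred <- pred$transform
  tibble::tibble(
    method = method,
    seed = pair$seed,
    crop_ratio = pair$provenance$crop_ratio,
    tre = target_registration_error(pair$landmarks_source, pair$landmarks_target,
                                    pred, pair$norm_map),
    mae_r = mae_rotation(pred, pair$gt_transform),
    mae_t = mae_translation(pred, pair$gt_transform, pair$norm_map),
    mae_r_geodesic = geodesic_rotation_error(pred, pair$gt_transform))
}

#' Aggregate per-pair metrics into a benchmark summary table
#'
#' Mean and sample (n-1) standard deviation of every metric per
#' method x crop-ratio cell, mirroring the usual partiality-table layout
#' (the ground-truth row is produced by evaluating the stored ground-truth
#' transform as the prediction).
#'
#' @param records tibble of per-pair metrics as returned by
#'   [evaluate_pair()] (rows bound together).
#' @return tibble with one row per method x crop ratio and
#'   `<metric>_mean` / `<metric>_sd` columns.
#' @export
aggregate_results <- function(records) {
  records |>
    dplyr::group_by(.data$method, .data$crop_ratio) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(c("tre", "mae_r", "mae_t", "mae_r_geodesic")),
      list(mean = ~mean(.x), sd = ~if (dplyr::n() > 1) stats::sd(.x) else 0)),
      n_pairs = dplyr::n(), .groups = "drop")
}

#' Format an aggregated summary as a partiality table
#'
#' One row per method, one `mean±sd` column block per crop ratio.
#'
#' @param summary tibble from [aggregate_results()].
#' @param digits decimals in the formatted cells.
#' @return a wide tibble of character cells.
#' @export
format_benchmark_table <- function(summary, digits = 2) {
  fmt <- function(m, s) sprintf(paste0("%.", digits, "f±%.", digits, "f"), m, s)
  summary |>
    dplyr::transmute(.data$method,
                     partiality = sprintf("%g%%", 100 * .data$crop_ratio),
                     `TRE (mm)` = fmt(.data$tre_mean, .data$tre_sd),
                     `MAE(R) (deg)` = fmt(.data$mae_r_mean, .data$mae_r_sd),
                     `MAE(t) (mm)` = fmt(.data$mae_t_mean, .data$mae_t_sd)) |>
    tidyr::pivot_wider(names_from = "partiality",
                       values_from = c("TRE (mm)", "MAE(R) (deg)", "MAE(t) (mm)"),
                       names_glue = "{partiality} {.value}")
}
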