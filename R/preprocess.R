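# Trait transformations taking raw-unit trial tables to the analysis scale:
# tracklength to body lengths via the species mean standard length, square
# root of time-in-middle, then global (all observations of all species
# pooled) mean-centering and scaling to standard deviation units (SDU).
# Global -- not per-species -- standardization puts traits on a common scale
# while preserving mean differences between species.

#' Scale tracklength to body lengths
#'
#' Divides a tracklength (recorded in cm) by the species mean standard length
#' (recorded in mm; the factor 10 converts units). The species mean -- not
#' each individual's own length -- is used, so size-dependent among-individual
#' variation within a species is retained rather than conflated with
#' personality.
#'
#' @param tl_cm tracklength in cm.
#' @param species_mean_sl mean standard length of the species in mm.
#' @return distance swum in (average) body lengths.
#' @export
to_body_lengths <- function(tl_cm, species_mean_sl) {
  if (!is.numeric(species_mean_sl) || any(species_mean_sl <= 0))
    stop("species_mean_sl must be positive")
  (tl_cm * 10) / species_mean_sl
}

#' Square-root transform of time-in-middle
#'
#' @param tim_s time spent in the middle zone, in seconds (>= 0).
#' @return square root of the input.
#' @export
transform_tim <- function(tim_s) {
  if (any(tim_s < 0)) stop("tim_s must be non-negative")
  sqrt(tim_s)
}

#' Standardize a trial table to global standard deviation units
#'
#' Applies the transformation pipeline in its fixed order -- body-length
#' scaling of TL, square root of TIM, then mean-centering and scaling of every
#' trait by its global (across all observations of all species) mean and
#' sample SD. After standardization each trait column has pooled mean 0 and
#' pooled SD 1 while per-species means in general remain distinct.
#'
#' @param table raw-unit trial table (columns as written by [write_trials()]).
#' @param scaling optional scaling record from a previous call, to place new
#'   data on an existing scale instead of recomputing the global statistics.
#' @return list with `data` (the table with SDU trait columns `TL`, `Act`,
#'   `AC`, `TIM` replacing the raw trait columns) and `scaling` (per-trait
#'   global `center`/`scale` plus the per-species mean standard lengths),
#'   which permits an exact inverse via [invert_standardize()].
#' @export
global_standardize <- function(table, scaling = NULL) {
  stopifnot(all(c("species", "tl_cm", "act_pct", "ac_pct", "tim_s", "sl_mm")
                %in% names(table)))
  sl <- tapply(table$sl_mm, table$species, function(x) {
    u <- unique(x)
    if (length(u) != 1) stop("each species must have a single mean SL")
    u
  })
  sl <- sl[!is.na(sl)]
  tr <- data.frame(
    TL = to_body_lengths(table$tl_cm, table$sl_mm),
    Act = table$act_pct,
    AC = table$ac_pct,
    TIM = transform_tim(table$tim_s))
  if (any(!stats::complete.cases(tr))) stop("trial table has missing trait cells")
  if (is.null(scaling)) {
    if (nrow(tr) < 2) stop("need at least 2 observations")
    center <- vapply(tr, mean, 0)
    scale <- vapply(tr, sd, 0)
    bad <- names(scale)[scale <= 0]
    if (length(bad))
      stop("zero variance in trait(s): ", paste(bad, collapse = ", "))
    scaling <- list(center = center, scale = scale, species_sl = c(sl))
  }
  sdu <- sweep(sweep(as.matrix(tr), 2, scaling$center), 2, scaling$scale, "/")
  out <- cbind(
    table[intersect(c("species", "fish_id", "group", "order_in_group",
                      "repeat"), names(table))],
    as.data.frame(sdu))
  rownames(out) <- NULL
  list(data = out, scaling = scaling)
}

#' Invert global standardization back to raw units
#'
#' @param data SDU-scale table as produced by [global_standardize()].
#' @param scaling the matching scaling record.
#' @return raw-unit trial table (trait columns `tl_cm`, `act_pct`, `ac_pct`,
#'   `tim_s`, `sl_mm`).
#' @export
invert_standardize <- function(data, scaling) {
  tr <- sweep(sweep(as.matrix(data[oft_traits()]), 2, scaling$scale, "*"),
              2, scaling$center, "+")
  sl <- scaling$species_sl[as.character(data$species)]
  out <- cbind(
    data[intersect(c("species", "fish_id", "group", "order_in_group",
                     "repeat"), names(data))],
    data.frame(tl_cm = tr[, "TL"] * sl / 10,
               act_pct = tr[, "Act"],
               ac_pct = tr[, "AC"],
               tim_s = tr[, "TIM"]^2,
               sl_mm = sl))
  rownames(out) <- NULL
  out
}

#' Serialize / read a scaling record as plain text
#'
#' @param scaling a scaling record from [global_standardize()].
#' @param path file path.
#' @return `read_scaling` returns the scaling record.
#' @export
write_scaling <- function(scaling, path) {
  lines <- c(
    paste0("center\t", paste(names(scaling$center),
                             format(scaling$center, digits = 17),
                             sep = "=", collapse = "\t")),
    paste0("scale\t", paste(names(scaling$scale),
                            format(scaling$scale, digits = 17),
                            sep = "=", collapse = "\t")),
    paste0("species_sl\t", paste(names(scaling$species_sl),
                                 format(scaling$species_sl, digits = 17),
                                 sep = "=", collapse = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scaling
#' @export
read_scaling <- function(path) {
  lines <- readLines(path)
  parse_kv <- function(line) {
    parts <- strsplit(strsplit(line, "\t")[[1]][-1], "=", fixed = TRUE)
    stats::setNames(vapply(parts, function(p) as.numeric(p[2]), 0),
                    vapply(parts, `[`, "", 1))
  }
  list(center = parse_kv(lines[1]), scale = parse_kv(lines[2]),
       species_sl = parse_kv(lines[3]))
}
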