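#' Specific root length
#'
#' SRL = total fine-root length (m) / fine-root dry mass (g). Undefined
#' (with a warning) where the mass is zero.
#'
#' @param total_length_m total fine-root length, m.
#' @param dry_mass_g fine-root dry mass, g.
#' @return SRL in m g-1, vectorised.
#' @examples
#' srl(30, 0.5) # 60 m/g
#' @export
srl <- function(total_length_m, dry_mass_g) {
  if (any(total_length_m < 0 | dry_mass_g < 0, na.rm = TRUE)) {
    abort("root length and mass must be >= 0")
  }
  zero <- !is.na(dry_mass_g) & dry_mass_g == 0
  if (any(zero)) warn("SRL undefined where dry mass is zero; returning NA")
  ifelse(zero, NA_real_, total_length_m / dry_mass_g)
}

#' Specific root area
#'
#' SRA = projected fine-root area (m2) / fine-root dry mass (g). For
#' cylindrical roots of uniform diameter d, SRA = SRL x d exactly
#' (projected area of a cylinder = length x diameter).
#'
#' @param projected_area_m2 projected fine-root area, m2.
#' @param dry_mass_g fine-root dry mass, g.
#' @return SRA in m2 g-1, vectorised.
#' @export
sra <- function(projected_area_m2, dry_mass_g) {
  if (any(projected_area_m2 < 0 | dry_mass_g < 0, na.rm = TRUE)) {
    abort("root area and mass must be >= 0")
  }
  zero <- !is.na(dry_mass_g) & dry_mass_g == 0
  if (any(zero)) warn("SRA undefined where dry mass is zero; returning NA")
  ifelse(zero, NA_real_, projected_area_m2 / dry_mass_g)
}

#' Fine-root mass density of a core segment
#'
#' Mass of fine roots per unit soil volume: 1000 m / (pi (d/2)^2 h) in
#' mg cm-3. The default geometry is the ingrowth-core segment (4 cm
#' diameter, 10 cm height, ~125.66 cm3).
#'
#' @param dry_mass_g fine-root dry mass in the segment, g.
#' @param core_diameter_cm core diameter, cm.
#' @param segment_height_cm segment height, cm.
#' @return Mass density, mg cm-3.
#' @export
root_mass_density <- function(dry_mass_g, core_diameter_cm = 4,
                              segment_height_cm = 10) {
  if (core_diameter_cm <= 0 || segment_height_cm <= 0) {
    abort("core geometry must be positive")
  }
  volume <- pi * (core_diameter_cm / 2)^2 * segment_height_cm
  1000 * dry_mass_g / volume
}

#' Fine-root to shoot production ratio
#'
#' Root production is measured on the core footprint (pi (2 cm)^2) and
#' shoot production on a 1 m2 quadrat, so both masses are normalised to
#' per-unit-ground-area before division, making the ratio dimensionless
#' and invariant to the area unit. `normalize = FALSE` gives the raw
#' mass-over-mass ratio for compatibility with unnormalised reporting.
#'
#' @param root_mass_g fine-root dry mass 0-30 cm per core footprint, g.
#' @param shoot_mass_g aboveground dry biomass per quadrat, g (> 0).
#' @param core_area_m2 core footprint area, m2.
#' @param quadrat_area_m2 quadrat area, m2.
#' @param normalize normalise both masses to per-area before dividing.
#' @return R/S production ratio, dimensionless.
#' @export
rs_production <- function(root_mass_g, shoot_mass_g,
                          core_area_m2 = pi * 0.02^2, quadrat_area_m2 = 1,
                          normalize = TRUE) {
  if (any(shoot_mass_g <= 0, na.rm = TRUE)) {
    abort("shoot mass must be positive")
  }
  if (normalize) {
    (root_mass_g / core_area_m2) / (shoot_mass_g / quadrat_area_m2)
  } else {
    root_mass_g / shoot_mass_g
  }
}

#' Compute fine-root traits for a set of core records
#'
#' Adds SRL, SRA and mass density per record; when shoot samples are given
#' (per plot x period), the fine-root-to-shoot production ratio is computed
#' from the 0-30 cm mass sum of each plot x period.
#'
#' @param cores core records ([generate_root_cores()] schema or the
#'   equivalent columns).
#' @param shoots optional tibble with `plot`, `period`, `shoot_mass_g`.
#' @param ... passed to [rs_production()].
#' @return The cores with `srl_m_g`, `sra_m2_g`, `root_mass_density_mg_cm3`
#'   added and, when shoots are given, a per-plot `rs_production` column
#'   joined on.
#' @export
root_traits <- function(cores, shoots = NULL, ...) {
  assert_cols(cores, c("dry_mass_g", "total_length_m", "projected_area_m2"),
              "cores")
  out <- cores |>
    mutate(
      srl_m_g = srl(.data$total_length_m, .data$dry_mass_g),
      sra_m2_g = sra(.data$projected_area_m2, .data$dry_mass_g),
      root_mass_density_mg_cm3 = root_mass_density(.data$dry_mass_g)
    )
  if (!is.null(shoots)) {
    assert_cols(shoots, c("plot", "period", "shoot_mass_g"), "shoots")
    rs <- out |>
      group_by(.data$plot, .data$period) |>
      summarise(root_mass_0_30_g = sum(.data$dry_mass_g), .groups = "drop") |>
      inner_join(shoots, by = c("plot", "period")) |>
      mutate(rs_production = rs_production(.data$root_mass_0_30_g,
                                           .data$shoot_mass_g, ...)) |>
      select("plot", "period", "rs_production")
    out <- left_join(out, rs, by = c("plot", "period"))
  }
  out
}

#' Linear relation between a fine-root trait and uptake capacity
#'
#' Ordinary least-squares fit of per-layer maximum hourly uptake on one
#' root trait, pooled across layers with additive per-layer offsets (depth
#' enters as a fixed shift, so the trait slope is a within-profile
#' contrast). This is deliberately a simple estimator of the slope and its
#' sign; full mixed-effects treatment inference is out of scope here.
#'
#' @param traits trait records ([root_traits()] output) holding the
#'   response column; alternatively pass `rwu_max` records to join.
#' @param rwu_max optional [rwu_max()] records, joined on the shared key
#'   columns (plot/layer/period).
#' @param predictor one of `"mass_density"`, `"srl"`, `"sra"`,
#'   `"diameter"`.
#' @param response response column; auto-detected (`rwu_max_mm_h`, then
#'   `rwu_max_latent`) when `NULL`.
#' @return A `trait_relation` object: the lm fit, slope, standard error and
#'   data; see [tidy.trait_relation()] and [glance.trait_relation()].
#' @examples
#' cores <- generate_root_cores(scenario_config(seed = 4), n_plots = 6)
#' rel <- trait_rwu_relation(root_traits(cores), predictor = "srl")
#' tidy(rel)
#' @export
trait_rwu_relation <- function(traits, rwu_max = NULL,
                               predictor = c("mass_density", "srl", "sra",
                                             "diameter"),
                               response = NULL) {
  predictor <- match.arg(predictor)
  pred_col <- c(mass_density = "root_mass_density_mg_cm3", srl = "srl_m_g",
                sra = "sra_m2_g", diameter = "mean_diameter_mm")[[predictor]]
  dat <- as_tibble(traits)
  if (!is.null(rwu_max)) {
    keys <- intersect(intersect(c("plot", "plot_id", "period", "layer"),
                                names(dat)), names(rwu_max))
    if (length(keys) == 0L) abort("no shared key columns to join rwu_max on")
    dat <- inner_join(dat, rwu_max, by = keys)
  }
  response <- response %||%
    intersect(c("rwu_max_mm_h", "rwu_max_latent"), names(dat))[1]
  if (is.na(response) || !response %in% names(dat)) {
    abort("cannot find a response column; pass `response`")
  }
  assert_cols(dat, pred_col, "traits")
  dat <- dat[stats::complete.cases(dat[c(pred_col, response)]), ]
  if (nrow(dat) < 3L) abort("need at least 3 matched records")
  has_layers <- "layer" %in% names(dat) && length(unique(dat$layer)) > 1L
  fml <- stats::reformulate(c(pred_col, if (has_layers) "layer"),
                            response = response)
  fit <- lm(fml, data = dat)
  cf <- summary(fit)$coefficients
  slope <- if (pred_col %in% rownames(cf)) cf[pred_col, "Estimate"] else NA_real_
  se <- if (pred_col %in% rownames(cf)) cf[pred_col, "Std. Error"] else NA_real_
  if (is.na(slope) || stats::var(dat[[pred_col]]) == 0) {
    warn("predictor is constant: slope undefined")
    slope <- NA_real_
    se <- NA_real_
  }
  structure(
    list(fit = fit, predictor = predictor, predictor_col = pred_col,
         response = response, slope = slope, se = se, n = nrow(dat),
         data = dat),
    class = "trait_relation"
  )
}

#' @export
print.trait_relation <- function(x, ...) {
  cat(sprintf(
    "Trait-uptake relation: %s ~ %s (+ layer offsets)\n  n = %d, slope = %.4g (se %.3g)\n",
    x$response, x$predictor, x$n, x$slope, x$se
  ))
  invisible(x)
}

#' Tidy a trait-uptake relation
#'
#' @param x a `trait_relation`.
#' @param ... unused.
#' @return One row per model term: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.trait_relation <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"],
    statistic = cf[, "t value"],
    p.value = cf[, "Pr(>|t|)"]
  )
}

#' One-row summary of a trait-uptake relation
#'
#' @param x a `trait_relation`.
#' @param ... unused.
#' @return Tibble with `predictor`, `slope`, `se`, `r.squared`, `sigma`,
#'   `nobs`.
#' @export
glance.trait_relation <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    predictor = x$predictor,
    slope = x$slope,
    se = x$se,
    r.squared = s$r.squared,
    sigma = s$sigma,
    nobs = x$n
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
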