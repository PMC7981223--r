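#' Seasonal RSF surface
#'
#' Per-cell relative selection `w = exp(sum beta_k x_k)` from the final
#' (stage-2) model, with the intercept, random intercepts and the
#' release-site decay term omitted — the release-site effect is a nuisance
#' parameter of the translocation, not habitat. Grids are decay-transformed
#' with the alphas and standardized with the scaling record stored in the
#' fit, so raster predictions agree exactly with tabular [predict_w()].
#'
#' @param fit an `rsf_posterior` (stage-2 / fixed-scale fit).
#' @param stack covariate stack from [build_covariate_stack()] (raw,
#'   unstandardized grids; multi-scale grids at the selected radii).
#' @param selected_scales named character mapping each multi-scale variable
#'   to its selected `var@radius` column (e.g. from [two_stage_fit()]).
#' @param drop_terms coefficient names excluded from the surface.
#' @return List of class `rsf_surface`: `w` ([raster_grid()]), `drop_terms`.
#' @export
rsf_surface <- function(fit, stack, selected_scales = NULL,
                        drop_terms = "release") {
  beta <- colMeans(as.matrix(fit)[, fit$coef_names, drop = FALSE])
  beta <- beta[setdiff(names(beta), drop_terms)]
  template <- stack$grids[[1]]

  cols <- list()
  for (nm in names(beta)) {
    base <- sub("\\^2$", "", nm)
    src <- if (base %in% names(stack$grids)) base
           else if (!is.null(selected_scales) && base %in% names(selected_scales))
             selected_scales[[base]]
           else stop("covariate stack has no grid for model term ", nm)
    g <- stack$grids[[src]]
    if (is.null(g)) stop("covariate stack has no grid for model term ", nm)
    stopifnot_same_geometry(template, g)
    v <- as.vector(g$values)
    if (base %in% names(fit$alphas)) v <- decay_transform(v, fit$alphas[[base]])
    sc <- fit$scaling[fit$scaling$column == base, ]
    if (nrow(sc) != 1) stop("scaling record mismatch for ", base)
    v <- (v - sc$mean) / sc$sd
    if (grepl("\\^2$", nm)) {
      sq <- fit$scaling[fit$scaling$column == nm, ]
      if (nrow(sq) == 1) v <- (v^2 - sq$mean) / sq$sd else v <- v^2
    }
    cols[[nm]] <- v
  }
  eta <- Reduce(`+`, Map(`*`, cols, beta))
  w <- raster_grid(matrix(exp(eta), nrow = nrow(template$values)),
                   template$xmin, template$ymin, template$cellsize)
  structure(list(w = w, drop_terms = drop_terms, kind = "w"),
            class = "rsf_surface")
}

#' Logistic transform of an RSF surface
#'
#' `p = w / (1 + w)`, strictly increasing in `w`, mapping the relative
#' selection index into (0, 1) for compositing; `w = 1` (a cell at the
#' standardized covariate mean) maps to 0.5.
#'
#' @param surface an `rsf_surface` (or a `w` [raster_grid()]).
#' @return An `rsf_surface` holding the `p` grid.
#' @export
logistic_surface <- function(surface) {
  g <- if (inherits(surface, "rsf_surface")) surface$w else surface
  if (any(g$values <= 0, na.rm = TRUE)) stop("w must be positive")
  p <- g
  p$values <- g$values / (1 + g$values)
  structure(list(w = p, drop_terms = if (inherits(surface, "rsf_surface"))
    surface$drop_terms else character(0), kind = "p"), class = "rsf_surface")
}

#' Annual composite habitat surface
#'
#' Cellwise geometric mean of the three logistic-transformed seasonal
#' surfaces (nesting, brood rearing, summer); a relative index of selection
#' across life stages. Nodata in any input propagates.
#'
#' @param p_nest,p_brood,p_summer aligned `rsf_surface`s (or grids) on the
#'   (0, 1) scale.
#' @return An `rsf_surface` with the composite grid.
#' @export
annual_composite <- function(p_nest, p_brood, p_summer) {
  gs <- lapply(list(p_nest, p_brood, p_summer), function(s)
    if (inherits(s, "rsf_surface")) s$w else s)
  stopifnot_same_geometry(gs[[1]], gs[[2]])
  stopifnot_same_geometry(gs[[1]], gs[[3]])
  vals <- lapply(gs, `[[`, "values")
  if (any(unlist(vals) <= 0 | unlist(vals) >= 1, na.rm = TRUE))
    stop("seasonal surfaces must lie in (0, 1); apply logistic_surface() first")
  out <- gs[[1]]
  out$values <- (vals[[1]] * vals[[2]] * vals[[3]])^(1 / 3)
  structure(list(w = out, drop_terms = character(0), kind = "p"),
            class = "rsf_surface")
}

#' Habitat change between shrub epochs
#'
#' Difference of the logistic-transformed RSF surfaces computed from two
#' covariate stacks that differ only in the shrub layer (each smoothed at
#' the selected scale): `delta = p(late) - p(early)`, cellwise in (-1, 1).
#' Negative values mark habitat lost with shrub decline; swapping the epochs
#' negates the surface exactly.
#'
#' @param fit stage-2 `rsf_posterior`.
#' @param stack_late,stack_early covariate stacks for the two shrub epochs.
#' @param selected_scales named selected `var@radius` columns.
#' @param drop_terms terms excluded from the surfaces.
#' @return A [raster_grid()] of per-cell change.
#' @export
change_surface <- function(fit, stack_late, stack_early,
                           selected_scales = NULL, drop_terms = "release") {
  for (nm in names(stack_late$grids)) {
    if (grepl("^shrub", nm)) next
    a <- stack_late$grids[[nm]]; b <- stack_early$grids[[nm]]
    if (is.null(b) || !same_geometry(a, b) ||
        !isTRUE(all.equal(a$values, b$values)))
      stop("epoch stacks differ in non-shrub layer: ", nm)
  }
  p_late <- logistic_surface(rsf_surface(fit, stack_late, selected_scales,
                                         drop_terms))
  p_early <- logistic_surface(rsf_surface(fit, stack_early, selected_scales,
                                          drop_terms))
  out <- p_late$w
  out$values <- p_late$w$values - p_early$w$values
  out
}

#' Mean habitat change by selection class
#'
#' Classifies the selection surface `p` into quantile classes of (near)
#' equal cell counts and reports the mean change per class — the summary
#' behind statements like "highly selected areas experienced the greatest
#' losses".
#'
#' @param delta change [raster_grid()] from [change_surface()].
#' @param p selection surface (`rsf_surface` or grid) on (0, 1).
#' @param n_classes number of quantile classes.
#' @return `data.frame` with `class`, `p_lower`, `p_upper`, `n_cells`,
#'   `mean_delta`.
#' @export
change_by_selection_class <- function(delta, p, n_classes = 5) {
  pg <- if (inherits(p, "rsf_surface")) p$w else p
  stopifnot_same_geometry(delta, pg)
  pv <- as.vector(pg$values)
  dv <- as.vector(delta$values)
  ok <- !is.na(pv) & !is.na(dv)
  brk <- stats::quantile(pv[ok], probs = seq(0, 1, length.out = n_classes + 1))
  brk[1] <- -Inf; brk[length(brk)] <- Inf
  cls <- cut(pv[ok], unique(brk), labels = FALSE)
  data.frame(
    class = sort(unique(cls)),
    p_lower = as.vector(stats::quantile(pv[ok], seq(0, 1, length.out = n_classes + 1)))[-(n_classes + 1)],
    p_upper = as.vector(stats::quantile(pv[ok], seq(0, 1, length.out = n_classes + 1)))[-1],
    n_cells = as.vector(table(cls)),
    mean_delta = as.vector(tapply(dv[ok], cls, mean)))
}

#' @export
print.rsf_surface <- function(x, ...) {
  cat(sprintf("<rsf_surface> (%s scale)\n", x$kind))
  print(x$w)
  invisible(x)
}
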