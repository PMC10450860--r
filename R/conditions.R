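#' Thermodynamic condition sets
#'
#' A `condition_set` fixes the external thermodynamic parameters at which a
#' potential graph or kinetic model is evaluated: ligand concentrations (molar,
#' relative to the standard state c0 = 1 M), pH, membrane voltage and
#' temperature.
#'
#' Protons are always specified through pH, never as a raw concentration; the
#' conversion \[H+\]/c0 = 10^(-pH) is applied wherever a proton concentration
#' is needed. For membrane-transporter models the two baths may differ:
#' `concentrations` entries and `pH` may be length-2 named vectors
#' `c(in = ..., out = ...)`; a scalar applies to both sides.
#'
#' @param concentrations named list or vector of molar concentrations; each
#'   element is a scalar (single bath) or a named `c(in=, out=)` pair.
#' @param pH scalar or `c(in=, out=)` pair; may be `NULL` for proton-free
#'   models.
#' @param voltage membrane potential \eqn{\Delta\Psi = \Psi_{in} - \Psi_{out}}
#'   in volts.
#' @param temperature kelvin; sets the thermal energy used when converting the
#'   voltage to kT units. Free energies themselves are always in kT.
#' @return an object of class `condition_set`.
#' @examples
#' condition_set(concentrations = list("Na+" = 0.1), pH = 8)
#' @export
condition_set <- function(concentrations = list(), pH = NULL, voltage = 0,
                          temperature = 298.15) {
  concentrations <- lapply(concentrations, function(x) {
    x <- unlist(x)
    if (any(!is.finite(x)) || any(x <= 0))
      validation_error("concentrations must be strictly positive and finite")
    x
  })
  if (length(concentrations) &&
      (is.null(names(concentrations)) || any(!nzchar(names(concentrations)))))
    validation_error("all concentrations must be named by ligand")
  if (!is.null(pH)) pH <- unlist(pH)
  if (!is.finite(temperature) || temperature <= 0)
    validation_error("temperature must be > 0")
  structure(list(concentrations = concentrations, pH = pH,
                 voltage = voltage, temperature = temperature),
            class = "condition_set")
}

#' @export
print.condition_set <- function(x, ...) {
  cat("<condition_set>\n")
  if (length(x$concentrations)) {
    for (nm in names(x$concentrations))
      cat("  [", nm, "] = ", paste(signif(x$concentrations[[nm]], 4), collapse = "/"),
          " M\n", sep = "")
  }
  if (!is.null(x$pH)) cat("  pH =", paste(signif(x$pH, 4), collapse = "/"), "\n")
  cat("  voltage =", x$voltage * 1e3, "mV, T =", x$temperature, "K\n")
  invisible(x)
}

# is this ligand the proton?
is_proton <- function(ligand) ligand %in% c("H+", "H", "proton")

# concentration at a *reference* condition: ligands it does not price default
# to the standard state (1 M; pH 0 when no pH is given)
reference_concentration <- function(cs, ligand, side = NA) {
  if (is_proton(ligand) && is.null(cs$pH)) return(1)
  if (!is_proton(ligand) && !ligand %in% names(cs$concentrations)) return(1)
  ligand_concentration(cs, ligand, side)
}

#' Concentration of a ligand under a condition set
#'
#' Returns \[X\]/c0 (dimensionless, c0 = 1 M) for `ligand` on membrane `side`.
#' Protons are resolved through the pH.
#'
#' @param cs a [condition_set()].
#' @param ligand ligand name.
#' @param side `NA` for a single bath, `"in"` or `"out"` for transporter
#'   models. Falls back to the bath value when no side-specific entry exists.
#' @return dimensionless concentration ratio.
#' @export
ligand_concentration <- function(cs, ligand, side = NA) {
  pick_side <- function(v) {
    if (length(v) == 1L) return(unname(v))
    if (is.na(side) || is.null(names(v)))
      validation_error(paste0("side-specific values given for '", ligand,
                              "' but no side requested"))
    if (!side %in% names(v))
      validation_error(paste0("missing side '", side, "' for ligand '", ligand, "'"))
    unname(v[[side]])
  }
  if (is_proton(ligand)) {
    if (is.null(cs$pH))
      validation_error("condition set has no pH but a proton concentration is required")
    return(10^(-pick_side(cs$pH)))
  }
  if (!ligand %in% names(cs$concentrations))
    validation_error(paste0("no concentration given for ligand '", ligand, "'"))
  pick_side(cs$concentrations[[ligand]])
}

#' Load conditions from a YAML file
#'
#' Reads keys `concentrations` (map ligand -> molar value, or map with `in` /
#' `out` subkeys), `pH`, `voltage_mV` and `temperature_K`. Scalar entries give
#' a single [condition_set()]; list-valued entries produce the full Cartesian
#' grid of conditions (a list of `condition_set` with attribute `"axes"`).
#'
#' @param path YAML file path.
#' @return a `condition_set`, or a list of them for gridded input.
#' @export
load_conditions <- function(path) {
  if (!file.exists(path)) format_error(paste0("conditions file not found: ", path))
  y <- yaml::yaml.load_file(path)
  conc <- y$concentrations %||% list()
  axes <- list()
  flat <- list()
  add_axis <- function(name, values) axes[[name]] <<- values
  for (nm in names(conc)) {
    v <- conc[[nm]]
    if (is.list(v) && !is.null(names(v))) {    # in/out sub-map, possibly gridded
      for (sd in names(v)) {
        key <- paste0("conc:", nm, ":", sd)
        add_axis(key, unlist(v[[sd]]))
      }
    } else {
      add_axis(paste0("conc:", nm), unlist(v))
    }
  }
  if (!is.null(y$pH)) {
    if (is.list(y$pH) && !is.null(names(y$pH))) {
      for (sd in names(y$pH)) add_axis(paste0("pH:", sd), unlist(y$pH[[sd]]))
    } else add_axis("pH", unlist(y$pH))
  }
  add_axis("voltage", (unlist(y$voltage_mV) %||% 0) / 1e3)
  add_axis("temperature", unlist(y$temperature_K) %||% 298.15)

  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  build_one <- function(row) {
    conc_l <- list()
    pH <- NULL
    for (key in names(row)) {
      val <- row[[key]]
      parts <- strsplit(key, ":", fixed = TRUE)[[1]]
      if (parts[1] == "conc") {
        if (length(parts) == 3L) {
          cur <- conc_l[[parts[2]]] %||% c()
          cur[parts[3]] <- val
          conc_l[[parts[2]]] <- cur
        } else conc_l[[parts[2]]] <- val
      } else if (parts[1] == "pH") {
        if (length(parts) == 2L) {
          pH <- c(pH, stats::setNames(val, parts[2]))
        } else pH <- val
      }
    }
    condition_set(concentrations = conc_l, pH = pH,
                  voltage = row[["voltage"]], temperature = row[["temperature"]])
  }
  if (nrow(grid) == 1L) return(build_one(grid[1, , drop = FALSE]))
  out <- lapply(seq_len(nrow(grid)), function(i) build_one(grid[i, , drop = FALSE]))
  attr(out, "axes") <- axes[vapply(axes, length, 1L) > 1L]
  attr(out, "grid") <- grid
  out
}

#' Build a one-axis grid of condition sets
#'
#' Convenience for scans: vary a single quantity of a base condition set.
#'
#' @param base a [condition_set()].
#' @param vary one of `"pH"`, `"voltage"`, or a ligand name.
#' @param values numeric vector of grid values (molar for ligands, volts for
#'   voltage).
#' @param side optional side (`"in"`/`"out"`) for the varied quantity.
#' @return list of `condition_set` with attributes `"axis"` and `"values"`.
#' @export
condition_grid <- function(base, vary, values, side = NA) {
  out <- lapply(values, function(v) {
    cs <- base
    if (vary == "pH") {
      if (!is.na(side)) cs$pH[side] <- v else cs$pH <- v
    } else if (vary == "voltage") {
      cs$voltage <- v
    } else {
      if (!is.na(side)) cs$concentrations[[vary]][side] <- v
      else cs$concentrations[[vary]] <- v
    }
    cs
  })
  attr(out, "axis") <- if (is.na(side)) vary else paste0(vary, ":", side)
  attr(out, "values") <- values
  out
}

#' Observable curves (training data)
#'
#' Tabulated macroscopic observable curves such as mean site occupancy versus
#' pH, used as training data for the inverse Monte-Carlo fit.
#'
#' @param x,y numeric vectors of equal length; `x` must have no duplicates.
#' @param observable label describing what `y` is (e.g. `"site:N2"`).
#' @param xname name of the independent variable (default `"pH"`).
#' @return object of class `observable_curve`.
#' @export
observable_curve <- function(x, y, observable, xname = "pH") {
  if (length(x) != length(y)) validation_error("x and y lengths differ")
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (anyDuplicated(x)) validation_error("duplicate x values in observable curve")
  structure(list(x = x, y = y, observable = observable, xname = xname),
            class = "observable_curve")
}

#' Load observable curves from CSV
#'
#' Expects columns `x,y,observable`; one `observable_curve` is returned per
#' distinct observable label.
#'
#' @param path CSV file path.
#' @return named list of [observable_curve()] objects.
#' @export
load_curves <- function(path) {
  if (!file.exists(path)) format_error(paste0("curves file not found: ", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("x", "y", "observable"))
    if (!col %in% names(d)) format_error(paste0("curves file missing column '", col, "'"))
  out <- lapply(split(d, d$observable),
                function(s) observable_curve(s$x, s$y, s$observable[1]))
  out[unique(d$observable)]
}
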