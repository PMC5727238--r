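# Phantom-based calibration: the basis-material attenuation coefficients
# that parameterise the decomposition. The calibration phantom holds a PMMA
# rod (soft-tissue equivalent) and a tube of the staining solution; basis
# coefficients are the mean reconstructed attenuation over each material's
# region, per spectrum, and the air coefficients are the mean over
# phantom-free regions.

#' Create a calibration set
#'
#' Holds the per-spectrum attenuation coefficients (mm^-1) of the three
#' basis materials: staining solution, PMMA, and air. The 2x3 basis matrix
#' (rows LE/HE, columns stain/PMMA/air) is the coefficient matrix of the
#' voxel-wise decomposition system.
#'
#' @param stain,pmma,air Numeric length-2 vectors `c(LE, HE)` of attenuation
#'   coefficients in mm^-1.
#' @param kvp Optional numeric length-2 vector of peak tube voltages for the
#'   two spectra (kVp), metadata only.
#' @param agent Optional label of the staining agent (e.g. `"I2E"`,
#'   `"Gadovist"`).
#' @param region_sizes Optional named numeric vector of calibration region
#'   sizes in voxels (provenance metadata).
#' @return An object of class `calibration_set`.
#' @examples
#' cs <- default_calibration_set("iodine")
#' basis_matrix(cs)
#' conditioning(cs)
#' @export
calibration_set <- function(stain, pmma, air = c(0, 0), kvp = NULL,
                            agent = NULL, region_sizes = NULL) {
  for (v in list(stain, pmma, air)) {
    if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v))) {
      stop("each material needs finite c(LE, HE) coefficients", call. = FALSE)
    }
  }
  if (abs(air[1]) >= 0.1 * abs(pmma[1]) || abs(air[2]) >= 0.1 * abs(pmma[2])) {
    warning("air coefficients are not small relative to PMMA; ",
            "check the phantom-free regions", call. = FALSE)
  }
  structure(
    list(stain = as.numeric(stain), pmma = as.numeric(pmma),
         air = as.numeric(air), kvp = kvp, agent = agent,
         region_sizes = region_sizes),
    class = "calibration_set"
  )
}

#' @export
print.calibration_set <- function(x, ...) {
  cat("<calibration_set>",
      if (!is.null(x$agent)) paste0(" agent: ", x$agent), "\n", sep = "")
  m <- basis_matrix(x)
  cat(sprintf("  %-6s LE %.5f  HE %.5f  (mm^-1)\n",
              colnames(m), m[1, ], m[2, ]), sep = "")
  if (!is.null(x$kvp)) cat("  kVp:", paste(x$kvp, collapse = " / "), "\n")
  invisible(x)
}

#' @rdname calibration_set
#' @param calset A `calibration_set`.
#' @param materials Which materials to include as columns, in order.
#' @export
basis_matrix <- function(calset, materials = c("stain", "pmma", "air")) {
  stopifnot(inherits(calset, "calibration_set"))
  m <- vapply(materials, function(nm) calset[[nm]], numeric(2))
  rownames(m) <- c("LE", "HE")
  m
}

#' Synthetic default calibration sets
#'
#' Plausible micro-CT scale coefficients for an iodine-in-ethanol or a
#' gadolinium (Gadobutrol) staining solution against PMMA and air. These are
#' synthetic values for simulation and testing; real studies must calibrate
#' against their own phantom scans with [estimate_basis()].
#'
#' @param agent `"iodine"` or `"gadolinium"`.
#' @return A `calibration_set`.
#' @export
default_calibration_set <- function(agent = c("iodine", "gadolinium")) {
  agent <- match.arg(agent)
  if (agent == "iodine") {
    calibration_set(stain = c(0.50, 0.12), pmma = c(0.10, 0.07),
                    air = c(4e-4, 3e-4), kvp = c(40.2, 70.1),
                    agent = "I2E (synthetic defaults)")
  } else {
    calibration_set(stain = c(0.40, 0.20), pmma = c(0.08, 0.055),
                    air = c(4e-4, 3e-4), kvp = c(60.2, 140.0),
                    agent = "Gadovist (synthetic defaults)")
  }
}

#' Estimate basis coefficients from a dual-energy phantom scan
#'
#' Each basis coefficient is the arithmetic mean of the reconstructed
#' attenuation over that material's region, separately for the low- and
#' high-energy volume. Regions must be non-empty and pairwise disjoint.
#'
#' @param vol_le,vol_he `attenuation_volume`s of the calibration phantom.
#' @param regions Named list of logical masks with elements `stain`, `pmma`
#'   and `air`, congruent with the volumes.
#' @param trim Optional trimming fraction passed to [mean()] for
#'   artifact-laden regions (default 0, the plain mean).
#' @param kvp,agent Metadata stored in the result.
#' @return A `calibration_set` with region sizes recorded.
#' @export
estimate_basis <- function(vol_le, vol_he, regions, trim = 0,
                           kvp = NULL, agent = NULL) {
  stopifnot(is_attenuation_volume(vol_le), is_attenuation_volume(vol_he))
  check_same_shape(vol_le, vol_he)
  need <- c("stain", "pmma", "air")
  if (!all(need %in% names(regions))) {
    stop("'regions' must contain masks named ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  regions <- regions[need]
  for (nm in need) {
    check_congruent(vol_le, regions[[nm]], paste0("region '", nm, "'"))
    if (!any(regions[[nm]])) {
      stop("region '", nm, "' is empty", call. = FALSE)
    }
  }
  overlap <- regions$stain & regions$pmma | regions$stain & regions$air |
    regions$pmma & regions$air
  if (any(overlap)) stop("calibration regions overlap", call. = FALSE)
  sizes <- vapply(regions, sum, numeric(1))
  if (any(sizes < 100)) {
    warning("calibration region(s) smaller than 100 voxels: ",
            paste(names(sizes)[sizes < 100], collapse = ", "), call. = FALSE)
  }
  mu <- function(vol, m) mean(vol$data[m], trim = trim)
  calibration_set(
    stain = c(mu(vol_le, regions$stain), mu(vol_he, regions$stain)),
    pmma = c(mu(vol_le, regions$pmma), mu(vol_he, regions$pmma)),
    air = c(mu(vol_le, regions$air), mu(vol_he, regions$air)),
    kvp = kvp, agent = agent, region_sizes = sizes
  )
}

#' Spectral separation of a calibration set
#'
#' The decomposition is only well posed if the two spectra respond to the
#' stain and to PMMA in sufficiently different proportion. This computes the
#' 2-norm condition number of the 2x2 (stain, PMMA) system matrix after
#' normalising each column to unit length, so the value measures angular
#' separation of the material signatures, not their magnitudes. Collinear
#' signatures give `Inf` and a `"fail"` flag.
#'
#' @param calset A `calibration_set`.
#' @param threshold Warn threshold on the condition number (default 20).
#' @return A list with elements `condition`, `flag` (`"pass"`, `"warn"` or
#'   `"fail"`) and `threshold`.
#' @export
conditioning <- function(calset, threshold = 20) {
  A <- basis_matrix(calset, c("stain", "pmma"))
  norms <- sqrt(colSums(A^2))
  if (any(norms == 0)) {
    return(list(condition = Inf, flag = "fail", threshold = threshold))
  }
  An <- sweep(A, 2, norms, "/")
  sv <- svd(An)$d
  kappa <- if (sv[2] <= .Machine$double.eps * sv[1]) Inf else sv[1] / sv[2]
  flag <- if (!is.finite(kappa)) "fail" else if (kappa > threshold) "warn" else "pass"
  list(condition = kappa, flag = flag, threshold = threshold)
}

check_calset_conditioning <- function(calset) {
  cond <- conditioning(calset)
  if (cond$flag == "fail") {
    stop("calibration set is singular: the two spectra do not separate ",
         "the basis materials", call. = FALSE)
  }
  invisible(cond)
}

#' Read and write calibration sets as YAML
#'
#' Serialises the coefficients (mm^-1), spectra labels and provenance
#' metadata to a small YAML file.
#'
#' @param calset A `calibration_set`.
#' @param path File path ending in `.yaml`/`.yml`.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns a `calibration_set`.
#' @export
write_calibration <- function(calset, path) {
  stopifnot(inherits(calset, "calibration_set"))
  obj <- list(
    units = "mm^-1",
    spectra = list(low = "LE", high = "HE"),
    kvp = calset$kvp, agent = calset$agent,
    materials = list(stain = calset$stain, pmma = calset$pmma,
                     air = calset$air),
    region_sizes = as.list(calset$region_sizes)
  )
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$materials)) stop("not a calibration YAML: ", path,
                                   call. = FALSE)
  rs <- if (length(obj$region_sizes)) unlist(obj$region_sizes) else NULL
  calibration_set(
    stain = as.numeric(obj$materials$stain),
    pmma = as.numeric(obj$materials$pmma),
    air = as.numeric(obj$materials$air),
    kvp = if (!is.null(obj$kvp)) as.numeric(unlist(obj$kvp)) else NULL,
    agent = obj$agent, region_sizes = rs
  )
}
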