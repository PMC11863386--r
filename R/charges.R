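#' Residue topology with partial charges
#'
#' An ordered atom table (name, residue, partial charge in elementary
#' charge units, backbone flag, optional coordinates) together with the
#' neutral-form backbone reference charges used by the
#' charge-neutralization schemes: when a charged residue is "switched
#' off", its backbone atoms are reassigned the partial charges of the
#' neutral form of the residue from the force field, and side-chain
#' charges are transformed so the whole residue carries exactly zero net
#' charge.
#'
#' @param atoms data.frame with columns `atom_name`, `residue_id`,
#'   `residue_name`, `charge`, `is_backbone` (logical) and optionally
#'   `x`, `y`, `z` (Angstrom).
#' @param neutral_backbone named numeric vector mapping backbone atom
#'   names to their neutral-form charges.
#' @return an object of class `residue_topology`.
#' @export
residue_topology <- function(atoms, neutral_backbone = NULL) {
  req <- c("atom_name", "residue_id", "residue_name", "charge",
           "is_backbone")
  stopifnot(is.data.frame(atoms), all(req %in% names(atoms)))
  if (any(!nzchar(atoms$atom_name))) stop("atom_name must be nonempty")
  if (any(is.na(atoms$is_backbone))) {
    stop("every atom must carry a backbone flag")
  }
  structure(list(atoms = atoms, neutral_backbone = neutral_backbone),
            class = "residue_topology")
}

#' Net charge of a residue topology
#' @param residue a [residue_topology()].
#' @return sum of partial charges (e).
#' @export
residue_net_charge <- function(residue) {
  sum(residue$atoms$charge)
}

# installs neutral-form backbone charges; shared by both schemes
.install_neutral_backbone <- function(residue) {
  bb <- residue$atoms$is_backbone
  if (!any(!bb)) stop("residue has no side-chain atoms (scheme error)")
  nb <- residue$neutral_backbone
  if (is.null(nb)) {
    stop("neutral-form backbone reference charges missing (scheme error)")
  }
  miss <- setdiff(residue$atoms$atom_name[bb], names(nb))
  if (length(miss) > 0) {
    stop("no neutral-form reference charge for backbone atom(s): ",
         paste(miss, collapse = ", "), " (scheme error)")
  }
  residue$atoms$charge[bb] <- unname(nb[residue$atoms$atom_name[bb]])
  residue
}

#' Polar charge-neutralization scheme
#'
#' Backbone charges are replaced by the neutral-form reference values;
#' every side-chain charge is divided by 2 and then shifted by one
#' uniform per-atom constant so the whole residue sums to exactly zero.
#' Halving keeps the residue polar while avoiding unrealistic charges on
#' aliphatic groups; the uniform shift preserves the relative ordering
#' of the side-chain charges.
#'
#' @param residue a [residue_topology()] with at least one side-chain
#'   atom and neutral-form backbone references.
#' @return the transformed `residue_topology`; net charge is 0 to within
#'   1e-12 e. The applied shift is recorded in attribute
#'   `"polar_shift"`.
#' @export
apply_polar_scheme <- function(residue) {
  stopifnot(inherits(residue, "residue_topology"))
  residue <- .install_neutral_backbone(residue)
  bb <- residue$atoms$is_backbone
  sc <- residue$atoms$charge[!bb] / 2
  delta <- -(sum(residue$atoms$charge[bb]) + sum(sc)) / length(sc)
  residue$atoms$charge[!bb] <- sc + delta
  attr(residue, "polar_shift") <- delta
  residue
}

#' Apolar (zeroing) charge-neutralization scheme
#'
#' Backbone charges are replaced by the neutral-form reference values;
#' side-chain charges are rescaled by one common factor chosen so the
#' residue sums to exactly zero. When the required side-chain total is
#' itself zero the charges are set to zero outright (the limiting
#' convention), which effectively converts the residue into an apolar
#' one.
#'
#' @inheritParams apply_polar_scheme
#' @return the transformed `residue_topology` with attribute
#'   `"apolar_factor"` (the divisor applied, `Inf` in the zeroing
#'   limit).
#' @export
apply_apolar_scheme <- function(residue) {
  stopifnot(inherits(residue, "residue_topology"))
  residue <- .install_neutral_backbone(residue)
  bb <- residue$atoms$is_backbone
  target <- -sum(residue$atoms$charge[bb])
  sc_sum <- sum(residue$atoms$charge[!bb])
  if (abs(target) < 1e-12) {
    residue$atoms$charge[!bb] <- 0
    attr(residue, "apolar_factor") <- Inf
    return(residue)
  }
  if (abs(sc_sum) < 1e-12) {
    stop("side-chain charges sum to zero but a nonzero target is ",
         "required (infeasibility error)")
  }
  f <- sc_sum / target
  residue$atoms$charge[!bb] <- residue$atoms$charge[!bb] / f
  attr(residue, "apolar_factor") <- f
  residue
}

#' Restraint specification
#'
#' Positional restraints (atom, reference position, force constant) and
#' one-sided upper-wall distance restraints (atom pair, threshold,
#' force constant). Wall energy is \eqn{\frac12 k (d - d_0)^2} for
#' \eqn{d > d_0} and 0 otherwise.
#'
#' @param positional data.frame with columns `atom_name`, `residue_id`,
#'   `x`, `y`, `z`, `k`.
#' @param upper_walls data.frame with columns `pair`, `threshold`, `k`.
#' @return an object of class `restraint_spec`.
#' @export
restraint_spec <- function(positional = NULL, upper_walls = NULL) {
  if (is.null(positional)) {
    positional <- data.frame(atom_name = character(0),
                             residue_id = integer(0), x = numeric(0),
                             y = numeric(0), z = numeric(0),
                             k = numeric(0))
  }
  if (is.null(upper_walls)) {
    upper_walls <- data.frame(pair = character(0), threshold = numeric(0),
                              k = numeric(0))
  }
  stopifnot(all(positional$k > 0), all(upper_walls$k > 0),
            all(upper_walls$threshold > 0))
  structure(list(positional = positional, upper_walls = upper_walls),
            class = "restraint_spec")
}

#' Build positional restraints outside a radius
#'
#' Restrains every backbone atom farther than `radius` from `center`
#' (e.g. the center of the catalytic His imidazole ring) at its current
#' position, so that charge-modified systems stay structurally identical
#' outside the active-site region. Side-chain atoms are never
#' restrained.
#'
#' @param atoms data.frame of atoms with `x`, `y`, `z`, `is_backbone`,
#'   `atom_name`, `residue_id`.
#' @param center length-3 numeric, Angstrom.
#' @param radius Angstrom; default 7.
#' @param k force constant, kcal/mol/A^2; default 10.
#' @return a [restraint_spec()] with the positional entries.
#' @export
build_positional_restraints <- function(atoms, center, radius = 7,
                                        k = 10) {
  stopifnot(radius > 0, k > 0, length(center) == 3)
  if (!all(c("x", "y", "z") %in% names(atoms)) ||
      any(is.na(atoms[c("x", "y", "z")]))) {
    stop("atom positions missing (geometry error)")
  }
  d <- sqrt((atoms$x - center[1])^2 + (atoms$y - center[2])^2 +
              (atoms$z - center[3])^2)
  sel <- atoms$is_backbone & d > radius
  restraint_spec(positional = data.frame(
    atom_name = atoms$atom_name[sel], residue_id = atoms$residue_id[sel],
    x = atoms$x[sel], y = atoms$y[sel], z = atoms$z[sel],
    k = rep(k, sum(sel)), stringsAsFactors = FALSE))
}

#' Build hydrogen-bond upper-wall restraints from sampled distances
#'
#' One upper wall per donor-acceptor pair, placed at the requested
#' percentile of the pooled unbiased distance distribution (linear
#' interpolation between order statistics). Used to preserve the
#' hydrogen-bonding profile of a residue whose charges are rescaled.
#'
#' @param distance_samples named list of numeric distance series, one
#'   per atom pair.
#' @param percentile fraction in (0, 1); default 0.9.
#' @param k force constant, kcal/mol/A^2; default 20.
#' @return a [restraint_spec()] with the upper-wall entries.
#' @export
build_hbond_walls <- function(distance_samples, percentile = 0.9,
                              k = 20) {
  stopifnot(is.list(distance_samples), percentile > 0, percentile < 1,
            k > 0)
  if (any(vapply(distance_samples, length, integer(1)) == 0)) {
    stop("empty distance series (data error)")
  }
  thr <- vapply(distance_samples, function(d) {
    unname(stats::quantile(d, percentile, type = 7))
  }, numeric(1))
  restraint_spec(upper_walls = data.frame(
    pair = names(distance_samples), threshold = thr, k = k,
    row.names = NULL, stringsAsFactors = FALSE))
}

#' Upper-wall restraint energy
#'
#' @param d distance(s).
#' @param threshold wall position \eqn{d_0}.
#' @param k force constant.
#' @return \eqn{\frac12 k (d-d_0)^2} beyond the threshold, else 0;
#'   continuous and piecewise differentiable at \eqn{d_0}.
#' @export
wall_energy <- function(d, threshold, k) {
  ifelse(d > threshold, 0.5 * k * (d - threshold)^2, 0)
}

#' Read / write residue topology tables
#'
#' Tab-separated tables with columns `atom_name`, `residue_id`,
#' `residue_name`, `charge`, `backbone_flag` (0/1).
#'
#' @param path file path.
#' @return for the reader, a data.frame of atoms.
#' @export
read_topology <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "backbone_flag"] <- "is_backbone"
  df$is_backbone <- as.logical(df$is_backbone)
  df
}

#' @param atoms atom data.frame as in [residue_topology()].
#' @rdname read_topology
#' @export
write_topology <- function(atoms, path) {
  out <- atoms[c("atom_name", "residue_id", "residue_name", "charge",
                 "is_backbone")]
  names(out)[5] <- "backbone_flag"
  out$backbone_flag <- as.integer(out$backbone_flag)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Emit restraints as a PLUMED-dialect text block
#'
#' For interoperability with production inputs: upper walls become
#' `UPPER_WALLS` lines and positional restraints `POSITION ... KAPPA`
#' lines. The block is an echo for cross-checking, not a complete
#' production input.
#'
#' @param spec a [restraint_spec()].
#' @return character vector of lines.
#' @export
restraints_to_plumed <- function(spec) {
  stopifnot(inherits(spec, "restraint_spec"))
  lines <- character(0)
  uw <- spec$upper_walls
  for (i in seq_len(nrow(uw))) {
    lines <- c(lines, sprintf(
      "UPPER_WALLS ARG=d_%s AT=%.4f KAPPA=%.1f EXP=2 LABEL=uwall_%d",
      gsub("[^A-Za-z0-9]", "_", uw$pair[i]), uw$threshold[i], uw$k[i], i))
  }
  pr <- spec$positional
  for (i in seq_len(nrow(pr))) {
    lines <- c(lines, sprintf(
      "POSITION ATOM=%s_%d LABEL=p%d",
      pr$atom_name[i], pr$residue_id[i], i), sprintf(
      "RESTRAINT ARG=p%d.x,p%d.y,p%d.z AT=%.3f,%.3f,%.3f KAPPA=%.1f,%.1f,%.1f",
      i, i, i, pr$x[i], pr$y[i], pr$z[i], pr$k[i], pr$k[i], pr$k[i]))
  }
  lines
}

#' Restraints as native YAML
#' @param spec a [restraint_spec()].
#' @param path optional output file; if `NULL` the YAML string is
#'   returned.
#' @export
restraints_to_yaml <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "restraint_spec"))
  obj <- list(positional = if (nrow(spec$positional)) spec$positional else list(),
              upper_walls = if (nrow(spec$upper_walls)) spec$upper_walls else list())
  txt <- yaml::as.yaml(obj)
  if (is.null(path)) txt else writeLines(txt, path)
}

#' Standard backbone atom-name partition
#'
#' The conventional protein backbone set used to assign backbone flags
#' when a topology does not provide them.
#' @return character vector of atom names.
#' @export
backbone_atom_names <- function() c("N", "H", "CA", "HA", "C", "O")
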