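# Synthetic-data generators: endpoint tables with known extremes for the
# composite-index layer, and QSAR datasets where the activity is a known
# linear function of real similarity-field descriptors plus Gaussian
# noise, for the PLS layer. All generation is seeded (default 20220309).

#' Specification for a synthetic endpoint table
#'
#' @param n_compounds number of compounds (>= 2).
#' @param endpoints named list of \code{c(min, max)} ranges to draw raw
#'   values from (uniformly).
#' @param directions named indicator directions over the same endpoints.
#' @param weights named weight ratios.
#' @param seed RNG seed.
#' @return list of class \code{synthetic_endpoint_spec}.
#' @export
synthetic_endpoint_spec <- function(
    n_compounds = 13,
    endpoints = list(permittivity = c(1.0, 1.05),
                     lc50 = c(1e-5, 125),
                     logbcf = c(0.4, 3.9)),
    directions = c(permittivity = "positive", lc50 = "positive",
                   logbcf = "negative"),
    weights = c(permittivity = 25, lc50 = 23, logbcf = 52),
    seed = 20220309) {
  stopifnot(n_compounds >= 2,
            identical(sort(names(endpoints)), sort(names(directions))),
            identical(sort(names(endpoints)), sort(names(weights))))
  for (ep in names(endpoints)) {
    r <- endpoints[[ep]]
    if (length(r) != 2 || r[2] <= r[1]) {
      stop("degenerate range requested for endpoint '", ep, "'")
    }
  }
  structure(list(n_compounds = n_compounds, endpoints = endpoints,
                 directions = directions, weights = weights, seed = seed),
            class = "synthetic_endpoint_spec")
}

#' Generate a synthetic endpoint table with known ground truth
#'
#' Draws each endpoint uniformly from its range and pins both range
#' endpoints onto two compounds, so every column's extremes (and hence the
#' expected normalized 0/1 entries) are known exactly.
#'
#' @param spec a [synthetic_endpoint_spec()].
#' @return list with \code{table} (compound + raw endpoint columns) and
#'   \code{truth} (per-endpoint min/max and the compounds carrying them,
#'   directions, normalized weights).
#' @export
generate_endpoint_table <- function(spec = synthetic_endpoint_spec()) {
  stopifnot(inherits(spec, "synthetic_endpoint_spec"))
  set.seed(spec$seed)
  n <- spec$n_compounds
  tab <- data.frame(compound = sprintf("SYN%02d", seq_len(n)),
                    stringsAsFactors = FALSE)
  truth <- list()
  for (ep in names(spec$endpoints)) {
    r <- spec$endpoints[[ep]]
    v <- stats::runif(n, r[1], r[2])
    at <- sample(n, 2)        # pin the known extremes
    v[at[1]] <- r[1]; v[at[2]] <- r[2]
    tab[[ep]] <- v
    truth[[ep]] <- list(min = r[1], max = r[2],
                        argmin = tab$compound[at[1]],
                        argmax = tab$compound[at[2]])
  }
  list(table = tab,
       truth = c(truth, list(directions = spec$directions,
                             weights = weight_vector(spec$weights))))
}

#' Specification for a synthetic QSAR dataset
#'
#' @param n_mol number of molecules.
#' @param n_atoms atoms in the shared scaffold of the synthetic series.
#' @param n_var scaffold positions whose atom properties vary from
#'   molecule to molecule (the "substituent" positions of the analog
#'   series).
#' @param support_size number of descriptor columns carrying the true
#'   (nonzero) coefficients.
#' @param sigma Gaussian noise standard deviation on the activity.
#' @param box half-width (Angstrom) of the cube scaffold positions are
#'   drawn in.
#' @param jitter per-molecule coordinate noise (Angstrom), emulating
#'   imperfect conformer alignment.
#' @param seed RNG seed.
#' @return list of class \code{synthetic_qsar_spec}.
#' @export
synthetic_qsar_spec <- function(n_mol = 10, n_atoms = 8, n_var = 3,
                                support_size = 4, sigma = 0.02, box = 3,
                                jitter = 0.05, seed = 20220309) {
  stopifnot(n_mol >= 4, n_atoms >= 2, n_var >= 1, n_var < n_atoms,
            support_size >= 1, sigma >= 0, box > 0, jitter >= 0)
  structure(list(n_mol = n_mol, n_atoms = n_atoms, n_var = n_var,
                 support_size = support_size, sigma = sigma, box = box,
                 jitter = jitter, seed = seed),
            class = "synthetic_qsar_spec")
}

# Synthetic aligned analog series: one random scaffold point set shared by
# every molecule, with per-molecule atom properties redrawn at the n_var
# "substituent" positions and a small coordinate jitter. Mimics what a
# scaffold-aligned QSAR training set looks like to the field engine:
# near-constant descriptor columns away from the variable positions,
# informative variance next to them.
.synthetic_series <- function(spec) {
  n <- spec$n_atoms
  elems <- sample(c("C", "O", "N"), n, replace = TRUE,
                  prob = c(0.6, 0.25, 0.15))
  base <- data.frame(
    elem = elems,
    x = stats::runif(n, -spec$box, spec$box),
    y = stats::runif(n, -spec$box, spec$box),
    z = stats::runif(n, -spec$box, spec$box),
    formal = 0,
    charge = stats::rnorm(n, 0, 0.15),
    logp_inc = stats::rnorm(n, 0, 0.3),
    aromatic = FALSE,
    n_h = 0,
    radius = unname(.vdw_radii[elems]),
    donor = 0,
    acceptor = as.numeric(elems %in% c("N", "O")),
    stringsAsFactors = FALSE)
  var_at <- sample(n, spec$n_var)
  lapply(seq_len(spec$n_mol), function(i) {
    at <- base
    at$charge[var_at] <- stats::rnorm(spec$n_var, 0, 0.3)
    at$logp_inc[var_at] <- stats::rnorm(spec$n_var, 0, 0.6)
    at$radius[var_at] <- stats::runif(spec$n_var, 1.2, 2.0)
    at$x <- at$x + stats::rnorm(n, 0, spec$jitter)
    at$y <- at$y + stats::rnorm(n, 0, spec$jitter)
    at$z <- at$z + stats::rnorm(n, 0, spec$jitter)
    at$charge <- at$charge - mean(at$charge)   # neutral molecule
    structure(list(name = sprintf("SYNMOL%02d", i),
                   smiles = NA_character_, atoms = at,
                   bonds = data.frame(a1 = integer(0), a2 = integer(0),
                                      order = numeric(0)),
                   meta = list(seed = spec$seed, synthetic = TRUE)),
              class = "pae_mol")
  })
}

#' Generate a synthetic QSAR dataset with known coefficients
#'
#' Builds a scaffold-aligned synthetic analog series (a shared point-set
#' scaffold with per-molecule property variation at a few substituent
#' positions), runs it through the real similarity-field engine on a
#' shared grid, then draws a sparse true coefficient vector over the
#' descriptor columns (unit magnitude, random sign, on the most variable
#' columns) and sets \eqn{y = X\beta + \varepsilon},
#' \eqn{\varepsilon \sim N(0, \sigma^2)}.
#'
#' @param spec a [synthetic_qsar_spec()].
#' @param kinds field kinds to include.
#' @param spacing,margin grid geometry (Angstrom).
#' @param alpha Gaussian attenuation (1/Angstrom^2).
#' @return list with \code{block} (a \code{comsia_block}), \code{y},
#'   \code{beta} (full-length true coefficients), \code{support} (their
#'   column indices), \code{mols} and the spec.
#' @export
generate_qsar_dataset <- function(spec = synthetic_qsar_spec(),
                                  kinds = c("S", "E", "H"),
                                  spacing = 2, margin = 2, alpha = 0.3) {
  stopifnot(inherits(spec, "synthetic_qsar_spec"))
  set.seed(spec$seed)
  mols <- .synthetic_series(spec)
  grid <- build_grid(mols, margin = margin, spacing = spacing)
  block <- assemble_descriptors(mols, grid, kinds = kinds, alpha = alpha)
  sds <- apply(block$X, 2, stats::sd)
  eligible <- sample(which(sds > 0.5 * max(sds)))
  # keep the support identifiable: columns of a Gaussian field are locally
  # near-collinear, and opposite true signs on collinear columns would
  # cancel; admit a column only if it is distinguishable from the ones
  # already chosen
  support <- integer(0)
  for (j in eligible) {
    if (length(support) >= spec$support_size) break
    if (!length(support) ||
        max(abs(stats::cor(block$X[, j], block$X[, support]))) < 0.8) {
      support <- c(support, j)
    }
  }
  if (length(support) < spec$support_size) {
    stop("true-coefficient support does not fit on the lattice; ",
         "not enough informative, mutually distinguishable columns")
  }
  support <- sort(support)
  beta <- numeric(ncol(block$X))
  beta[support] <- sample(c(-1, 1), spec$support_size, replace = TRUE)
  y <- drop(block$X %*% beta) + stats::rnorm(spec$n_mol, 0, spec$sigma)
  list(block = block, y = y, beta = beta, support = support, mols = mols,
       spec = spec)
}
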