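# DAP derivative enumeration, effect prediction, decision-rule screening
# and binding-energy-delta reporting.
#
# Modification sites on diallyl phthalate (DAP):
#   site 1 — the aromatic ring position ortho to the ester pair,
#   site 2 — the terminal allyl carbon of one ester side chain.
# Both bear a replaceable hydrogen; derivatives are built by SMILES
# substitution into site-annotated scaffold templates and named
# DAP-<site>-<group> / DAP-1-<g1>-2-<g2> in the source tables' convention.

.dap_smiles <- "C(=C)COC(=O)c1ccccc1C(=O)OCC=C"
.dap_template_site1 <- "C(=C)COC(=O)c1cccc(%s)c1C(=O)OCC=C"
.dap_template_site2 <- "C(=C)COC(=O)c1ccccc1C(=O)OCC=C%s"
.dap_template_dual <- "C(=C)COC(=O)c1cccc(%s)c1C(=O)OCC=C%s"

#' The DAP scaffold and its modification-site templates
#' @return list with the parent SMILES and the site-annotated templates.
#' @export
dap_scaffold <- function() {
  list(smiles = .dap_smiles,
       site1 = .dap_template_site1,
       site2 = .dap_template_site2,
       dual = .dap_template_dual)
}

#' The packaged substituent library
#'
#' The 14 modification groups (halogens, thiol, alkyls, phenyl/benzyl,
#' nitro groups, methoxy, ester and vinyl) with attachment fragments
#' written as appendable SMILES.
#'
#' @return data frame with \code{name} and \code{fragment}.
#' @export
substituent_library <- function() {
  load_fixture("substituents")[, c("name", "fragment")]
}

#' Enumerate DAP derivatives over the modification sites
#'
#' Builds all single-site products (each site x each group) and,
#' for \code{arity} 2, all ordered dual-site products (site-1 group x
#' site-2 group), in deterministic order, deduplicated by canonical
#' SMILES. Names follow the \code{DAP-<site>-<group>} convention.
#'
#' @param groups substituent data frame (\code{name}, \code{fragment});
#'   defaults to the packaged library.
#' @param sites which sites to substitute (subset of 1:2).
#' @param arity modification arities to enumerate (subset of 1:2).
#' @param allow optional character vector of derivative names to keep
#'   (applied after enumeration), for reproducing a published shortlist.
#' @return data frame with \code{name}, \code{smiles} (as constructed) and
#'   \code{smiles_canonical}.
#' @export
enumerate_derivatives <- function(groups = substituent_library(),
                                  sites = c(1L, 2L), arity = c(1L, 2L),
                                  allow = NULL) {
  stopifnot(all(sites %in% 1:2), all(arity %in% 1:2),
            all(c("name", "fragment") %in% names(groups)))
  nm <- character(0); smi <- character(0)
  if (1L %in% arity) {
    for (s in sites) {
      tpl <- if (s == 1L) .dap_template_site1 else .dap_template_site2
      nm <- c(nm, sprintf("DAP-%d-%s", s, groups$name))
      smi <- c(smi, sprintf(tpl, groups$fragment))
    }
  }
  if (2L %in% arity && all(1:2 %in% sites)) {
    for (i in seq_len(nrow(groups))) {
      for (j in seq_len(nrow(groups))) {
        nm <- c(nm, sprintf("DAP-1-%s-2-%s", groups$name[i], groups$name[j]))
        smi <- c(smi, sprintf(.dap_template_dual, groups$fragment[i],
                              groups$fragment[j]))
      }
    }
  }
  canon <- unlist(run_rdkit(list(action = "canonical",
                                 smiles = as.list(smi))),
                  use.names = FALSE)
  bad <- which(is.na(canon) | canon == "NULL")
  if (length(bad)) {
    stop("invalid product SMILES for: ", paste(nm[bad], collapse = ", "))
  }
  out <- data.frame(name = nm, smiles = smi, smiles_canonical = canon,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$smiles_canonical), , drop = FALSE]
  if (!is.null(allow)) out <- out[out$name %in% allow, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent change relative to a reference value
#'
#' \eqn{(value - reference) / |reference| \times 100}; dividing by the
#' reference magnitude keeps the sign meaningful for negative references
#' such as binding free energies.
#'
#' @param reference nonzero reference value(s).
#' @param value new value(s).
#' @return percent change, full precision.
#' @export
percent_change <- function(reference, value) {
  if (any(reference == 0)) stop("percent change undefined for a zero reference")
  (value - reference) / abs(reference) * 100
}

#' The derivative screening decision rule
#'
#' One row per condition on the percent-change columns of a derivative
#' record table: comprehensive effect up, insulation not reduced, toxicity
#' endpoint up (a larger predicted endpoint means a less toxic compound)
#' and bioconcentration down.
#'
#' @return data frame with \code{column}, \code{op}, \code{value}.
#' @export
screen_rule <- function() {
  data.frame(
    column = c("change_comprehensive", "change_insulation",
               "change_toxicity", "change_enrichment"),
    op = c(">", ">=", ">", "<"),
    value = 0,
    stringsAsFactors = FALSE)
}

#' Apply a screening rule to derivative records
#'
#' Keeps records satisfying every rule term and reports, for each
#' rejected record, which terms failed. Screening is idempotent and
#' monotone: tightening any threshold can only shrink the passing set.
#'
#' @param records data frame carrying all rule columns.
#' @param rule rule table as from [screen_rule()].
#' @return list with \code{passed} (subset of \code{records}) and
#'   \code{audit} (data frame of rejected record names and their failed
#'   terms).
#' @export
apply_screen <- function(records, rule = screen_rule()) {
  missing_cols <- setdiff(rule$column, names(records))
  if (length(missing_cols)) {
    stop("records lack rule column(s): ", paste(missing_cols, collapse = ", "))
  }
  ops <- list(">" = `>`, ">=" = `>=`, "<" = `<`, "<=" = `<=`)
  pass <- matrix(TRUE, nrow(records), nrow(rule))
  for (k in seq_len(nrow(rule))) {
    f <- ops[[rule$op[k]]]
    if (is.null(f)) stop("unsupported operator: ", rule$op[k])
    val <- records[[rule$column[k]]]
    pass[, k] <- !is.na(val) & f(val, rule$value[k])
  }
  ok <- rowSums(pass) == nrow(rule)
  id <- if ("compound" %in% names(records)) records$compound
        else if ("name" %in% names(records)) records$name
        else as.character(seq_len(nrow(records)))
  audit <- do.call(rbind, lapply(which(!ok), function(i) {
    data.frame(compound = id[i],
               failed = paste(sprintf("%s %s %g", rule$column[!pass[i, ]],
                                      rule$op[!pass[i, ]],
                                      rule$value[!pass[i, ]]),
                              collapse = "; "),
               stringsAsFactors = FALSE)
  }))
  if (is.null(audit)) {
    audit <- data.frame(compound = character(0), failed = character(0))
  }
  list(passed = records[ok, , drop = FALSE], audit = audit)
}

#' Predict effect values for derivative structures
#'
#' Full prediction pipeline: embed and minimize each structure, assign
#' atom parameters, align its phthalate core to the model template,
#' evaluate descriptor rows under the training block's grid and scaling,
#' and apply each fitted effect model. Percent changes are reported
#' against the reference molecule's prediction through the identical
#' pipeline.
#'
#' @param records data frame with \code{name} and \code{smiles}.
#' @param models named list of \code{pls_model} objects (e.g.
#'   \code{comprehensive}, \code{insulation}, \code{toxicity},
#'   \code{enrichment}).
#' @param block the training \code{comsia_block}.
#' @param template the alignment template \code{pae_mol}.
#' @param reference name of the reference record; if absent from
#'   \code{records} its SMILES must be supplied.
#' @param reference_smiles SMILES of the reference molecule (defaults to
#'   DAP).
#' @param seed embedding seed.
#' @return \code{records} with a predicted-value and percent-change column
#'   per model (\code{pred_<model>}, \code{change_<model>}).
#' @export
predict_effects <- function(records, models, block, template,
                            reference = "DAP",
                            reference_smiles = .dap_smiles,
                            seed = 20220309) {
  stopifnot(all(c("name", "smiles") %in% names(records)),
            length(names(models)) == length(models))
  have_ref <- reference %in% records$name
  smiles <- records$smiles
  nms <- records$name
  if (!have_ref) {
    smiles <- c(reference_smiles, smiles)
    nms <- c(reference, nms)
  }
  mols <- .prepare_molecules(smiles, nms, seed, minimize = TRUE)
  mols <- lapply(mols, assign_atom_parameters)
  aligned <- lapply(mols, function(m) align_to_template(m, template)$mol)
  X <- transform_descriptors(block, aligned)
  for (mn in names(models)) {
    pred <- predict(models[[mn]], X)
    ref_val <- pred[[reference]]
    keepn <- records$name
    records[[paste0("pred_", mn)]] <- unname(pred[keepn])
    records[[paste0("change_", mn)]] <- unname(
      percent_change(ref_val, pred[keepn]))
  }
  records
}

#' Binding-free-energy deltas under an applied electric field
#'
#' From a table of binding free energies at 0 V and 5 V (kJ/mol), computes
#' each molecule's field-induced shift \eqn{\Delta G_{5V} - \Delta
#' G_{0V}}, the percent change relative to the reference molecule at each
#' field strength, and flags molecules whose field-on increase exceeds the
#' reference's — the insulation-enhancement criterion.
#'
#' @param table data frame with \code{compound}, \code{dg_0v},
#'   \code{dg_5v} (kJ/mol).
#' @param reference reference compound name, present in \code{table}.
#' @return data frame with \code{field_shift}, \code{change_0v},
#'   \code{change_5v} and \code{exceeds_reference}.
#' @export
binding_energy_deltas <- function(table, reference = "DAP") {
  stopifnot(all(c("compound", "dg_0v", "dg_5v") %in% names(table)))
  if (!reference %in% table$compound) {
    stop("reference '", reference, "' not present in the table")
  }
  ref <- table[table$compound == reference, ]
  if (anyNA(c(ref$dg_0v, ref$dg_5v))) {
    stop("reference lacks a value at one field strength")
  }
  shift <- table$dg_5v - table$dg_0v
  ref_shift <- ref$dg_5v - ref$dg_0v
  data.frame(
    compound = table$compound,
    dg_0v = table$dg_0v,
    dg_5v = table$dg_5v,
    field_shift = shift,
    change_0v = ifelse(table$compound == reference, NA,
                       percent_change(ref$dg_0v, table$dg_0v)),
    change_5v = ifelse(table$compound == reference, NA,
                       percent_change(ref$dg_5v, table$dg_5v)),
    exceeds_reference = table$compound != reference & shift > ref_shift,
    stringsAsFactors = FALSE)
}
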