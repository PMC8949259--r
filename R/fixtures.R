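# Packaged data fixtures: the published endpoint, prediction, docking and
# binding-energy tables, the curated PAE SMILES and the substituent library.
# Files are plain CSV under inst/extdata and content-hashed at load time.

.fixture_manifest <- c(
  table1       = "31f2e43795e5eecabd0b89c65566a789",
  table2       = "a77181d15acc827789ef435b59fe6ace",
  table4       = "015e1b3e97907b131e8c825dd84fa826",
  table5       = "644bde8ccb10c54ef9c0762360979080",
  table6       = "c4dd94f48d7d51fc3fb03efef6e8b336",
  pae_smiles   = "6ea08be84e7fe0c6cc46cdf2afcebc0e",
  substituents = "f08583fb4bc1e4c27aeccc7eca61985a"
)

#' Load a packaged data fixture
#'
#' Fixtures ship with the package as commented CSV files:
#' \describe{
#'   \item{table1}{raw permittivity / fish LC50 / logBCF endpoints, 13 PAEs}
#'   \item{table2}{printed normalized indicators and comprehensive index I}
#'   \item{table4}{QSAR-predicted effects of DAP and 30 derivatives with
#'     percent changes}
#'   \item{table5}{docking scores of DAP and 4 shortlisted derivatives}
#'   \item{table6}{binding free energies at 0 V and 5 V applied field}
#'   \item{pae_smiles}{curated SMILES of the 13 PAEs}
#'   \item{substituents}{the 14-group substituent library}
#' }
#'
#' @param name fixture name, one of the above.
#' @param checksum verify the file's md5 against the packaged manifest.
#' @return data frame.
#' @export
load_fixture <- function(name, checksum = TRUE) {
  if (!name %in% names(.fixture_manifest)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(.fixture_manifest), collapse = ", "))
  }
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "paedesign", mustWork = TRUE)
  if (checksum) {
    got <- unname(tools::md5sum(path))
    if (!identical(got, unname(.fixture_manifest[name]))) {
      stop("checksum mismatch for fixture '", name, "'")
    }
  }
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE)
}

#' Default endpoint metadata for the PAE composite index
#'
#' Indicator directions (permittivity and LC50 positive, logBCF negative)
#' and the 25:23:52 weight ratio used to aggregate insulation, toxicity and
#' bioconcentration.
#'
#' @return list with \code{directions} and \code{weights}, both named by
#'   the table1 endpoint columns.
#' @export
pae_index_config <- function() {
  list(
    directions = c(permittivity = "positive", lc50 = "positive",
                   logbcf = "negative"),
    weights = c(permittivity = 25, lc50 = 23, logbcf = 52)
  )
}
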