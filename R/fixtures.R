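# Packaged worked-example tables. Files are shipped verbatim (typographic
# minus U+2212 and primes preserved); numeric columns are normalized to ASCII
# at parse time and integrity is checked against a frozen md5 before use.

.fixture_files <- c(
  table1 = "table1_gene_prioritization.tsv",
  table2 = "table2_docking.tsv",
  md_energies = "md_dgbind_energies.tsv"
)

.fixture_md5 <- c(
  table1 = "54f235695998998295012eb05d8b3581",
  table2 = "e850a8908032dc08351af6b228f6ffb2",
  md_energies = "a9ae4b03b7e4a7f32eb63b0cd544e751"
)

.ascii_minus <- function(x) gsub("−", "-", x)

#' Normalize typographic characters in compound names
#'
#' Maps prime (U+2032) and double prime (U+2033) to ASCII apostrophe and
#' double quote so that compound names can be compared reliably across
#' sources; the original spelling should be kept for display.
#'
#' @param x Character vector of compound names.
#' @return Character vector with typographic primes replaced.
#' @export
normalize_compound_names <- function(x) {
  x <- gsub("′", "'", x)
  gsub("″", "\"", x)
}

#' Load a packaged worked-example fixture
#'
#' Three plain-text fixtures ship with the package: `"table1"`, the 20-row
#' gene prioritization table (rank, gene, pathway, adjusted p, log2 fold
#' change, FPKM, pathway-relevance weight, composite score); `"table2"`, the
#' 50-row docking result table (10 compounds for each of the five protein
#' targets, with docking score and MM-GBSA binding free energy in kcal/mol);
#' and `"md_energies"`, the 15 per-triple molecular-dynamics-stage MM-GBSA
#' energies used for assay-candidate selection. File integrity is verified
#' against a stored checksum at every load.
#'
#' @param name One of `"table1"`, `"table2"`, `"md_energies"`.
#' @return A data.frame. `table2` and `md_energies` gain a `compound_norm`
#'   column with typographic primes normalized via
#'   [normalize_compound_names()]; the `compound` column keeps the original
#'   display spelling.
#' @examples
#' t1 <- load_fixture("table1")
#' t1[1, c("gene", "p_adjust", "fpkm", "score")]
#' @export
load_fixture <- function(name = c("table1", "table2", "md_energies")) {
  name <- match.arg(name)
  path <- system.file("extdata", .fixture_files[[name]], package = "netprio")
  if (!nzchar(path) || !file.exists(path))
    stop(sprintf("fixture file for '%s' is missing from the installation", name))
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, .fixture_md5[[name]]))
    stop(sprintf("fixture '%s' failed its integrity check (md5 %s)", name, md5))

  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8", quote = "")
  num_cols <- switch(name,
    table1 = c("p_adjust", "log2fc", "fpkm", "relevance", "score"),
    table2 = c("mz", "rt_min", "docking_score", "dg_bind"),
    md_energies = "dg_bind_md"
  )
  for (cl in num_cols) df[[cl]] <- as.numeric(.ascii_minus(df[[cl]]))
  if (anyNA(df[num_cols]))
    stop(sprintf("fixture '%s' contains unparseable numeric fields", name))
  if (name == "table1" && nrow(df) != 20L)
    stop("table1 fixture must have exactly 20 rows")
  if (name == "table2" && nrow(df) != 50L)
    stop("table2 fixture must have exactly 50 rows")
  if (name %in% c("table2", "md_energies"))
    df$compound_norm <- normalize_compound_names(df$compound)
  df
}
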