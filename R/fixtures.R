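# Packaged reference tables: the published day-13 miRNA
# differential-expression table, the reporter cloning / qRT-PCR primer
# table, and the mature miR-320c sequence (miRBase MIMAT0005793). Files
# live under inst/extdata and are integrity-checked on load.

fixture_md5 <- c(
  table1_mirna_day13.tsv = "c0c34244b5d88786440f2236e2d79a58",
  table2_cloning_primers.tsv = "4c803512d83c21356024500796569ed6",
  table2_qpcr_primers.tsv = "bca8ce01341425668c7c9fb422ea689d",
  mir320c_mature.fasta = "9ed64fc11c1ded2330ba5418c8626fca"
)

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "mirtriprong")
  if (path == "") stop("packaged fixture not found: ", file, call. = FALSE)
  got <- unname(tools::md5sum(path))
  if (!identical(got, unname(fixture_md5[[file]]))) {
    stop("checksum mismatch for packaged fixture ", file, call. = FALSE)
  }
  path
}

#' Load the packaged reference tables
#'
#' Returns the published tables as typed records, verbatim:
#' * `table1`: the 38-row day-13 vs day-0 miRNA differential-expression
#'   table (a `mirna_de_table`);
#' * `cloning_primers`: named list of [primer_pair()]s (`RUNX2_wt_UTR`,
#'   `RUNX2_mut_UTR`) for the luciferase reporter inserts, lower-case
#'   letters flagging mutated seed positions;
#' * `qpcr_primers`: data frame of qRT-PCR primer sequences;
#' * `mir320c`: the mature miR-320c sequence (RNA, named).
#'
#' File checksums are verified; a mismatch is a hard error.
#'
#' @return named list as described.
#' @export
#' @examples
#' fx <- load_fixtures()
#' nrow(fx$table1)
#' seed_of(fx$mir320c)
load_fixtures <- function() {
  table1 <- read_mirna_de_tsv(fixture_path("table1_mirna_day13.tsv"))

  cp <- read_tsv(fixture_path("table2_cloning_primers.tsv"))
  cloning <- lapply(split(cp, cp$name), function(d) {
    primer_pair(d$sequence[d$direction == "F"],
                d$sequence[d$direction == "R"],
                name = d$name[1])
  })

  qp <- read_tsv(fixture_path("table2_qpcr_primers.tsv"))
  mir <- read_mirna_fasta(fixture_path("mir320c_mature.fasta"))
  list(table1 = table1, cloning_primers = cloning, qpcr_primers = qp,
       mir320c = mir)
}
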