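# File interfaces: FASTA for references (via Biostrings), TSV collapsed
# libraries plus a samples CSV, RIN / delta-Ct CSV, YAML config. All
# writers format numbers explicitly so identical runs give byte-identical
# artifacts.

#' Write a reference set as per-class FASTA files
#'
#' One file per class; headers carry `class=`, and where relevant
#' `species=`, `category=`, `aa=`, `intron=`, `mito=` attributes.
#'
#' @param refs a `pmi_refs` object.
#' @param dir output directory (created if needed).
#' @return invisibly the vector of files written.
#' @export
write_reference_fasta <- function(refs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- function(seqs, headers, file) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- headers
    Biostrings::writeXStringSet(x, filepath = file.path(dir, file), width = 80)
    file
  }
  pre <- refs$pre_trnas
  files <- c(
    fa(refs$host_genome,
       paste0(names(refs$host_genome), " class=host_genome"), "host_genome.fa"),
    fa(pre$seq,
       sprintf("%s class=pre_trna aa=%s mito=%s intron=%s", pre$id, pre$aa,
               tolower(pre$mito),
               ifelse(is.na(pre$intron_start), "none",
                      paste0(pre$intron_start, "-", pre$intron_end))),
       "pre_trna.fa"),
    fa(unname(refs$mature_trnas),
       paste0(names(refs$mature_trnas), " class=mature_trna"), "mature_trna.fa"),
    fa(unname(refs$rrnas), paste0(names(refs$rrnas), " class=rrna"), "rrna.fa"),
    fa(unname(refs$yrnas), paste0(names(refs$yrnas), " class=yrna"), "yrna.fa"),
    fa(unname(refs$mirnas), paste0(names(refs$mirnas), " class=mirna"),
       "mirna.fa"),
    fa(unname(refs$pirnas), paste0(names(refs$pirnas), " class=pirna"),
       "pirna.fa"),
    fa(unname(refs$snornas), paste0(names(refs$snornas), " class=snorna"),
       "snorna.fa"),
    fa(unname(refs$bacterial_genomes),
       sprintf("%s class=bacterial_genome species=%s",
               names(refs$bacterial_genomes), names(refs$bacterial_genomes)),
       "bacterial_genome.fa"),
    fa(refs$bacterial_cds$seq,
       sprintf("%s class=bacterial_cds species=%s category=\"%s\"",
               refs$bacterial_cds$id, refs$bacterial_cds$species,
               refs$bacterial_cds$category),
       "bacterial_cds.fa"))
  invisible(file.path(dir, files))
}

#' Read a reference set back from a FASTA directory
#'
#' Counterpart of [write_reference_fasta()].
#'
#' @param dir directory containing the per-class FASTA files.
#' @return a `pmi_refs` object (without filler-block bookkeeping).
#' @export
read_reference_fasta <- function(dir) {
  rd <- function(file) {
    x <- Biostrings::readDNAStringSet(file.path(dir, file))
    seqs <- as.character(x)
    ids <- sub(" .*$", "", names(x))
    setNames(seqs, ids)
  }
  hdr_attr <- function(file, attr) {
    x <- Biostrings::readDNAStringSet(file.path(dir, file))
    m <- regmatches(names(x),
                    regexpr(sprintf('%s=("[^"]*"|\\S+)', attr), names(x)))
    gsub('"', "", sub(sprintf("^%s=", attr), "", m))
  }
  pre_seq <- rd("pre_trna.fa")
  intron <- hdr_attr("pre_trna.fa", "intron")
  a <- ifelse(intron == "none", NA, sub("-.*", "", intron))
  b <- ifelse(intron == "none", NA, sub(".*-", "", intron))
  pre_trnas <- data.frame(
    id = names(pre_seq), seq = unname(pre_seq),
    intron_start = as.integer(a), intron_end = as.integer(b),
    aa = hdr_attr("pre_trna.fa", "aa"),
    mito = hdr_attr("pre_trna.fa", "mito") == "true",
    stringsAsFactors = FALSE)
  cds_seq <- rd("bacterial_cds.fa")
  structure(list(
    host_genome = rd("host_genome.fa"),
    pre_trnas = pre_trnas,
    mature_trnas = rd("mature_trna.fa"),
    rrnas = rd("rrna.fa"), yrnas = rd("yrna.fa"), mirnas = rd("mirna.fa"),
    pirnas = rd("pirna.fa"), snornas = rd("snorna.fa"),
    bacterial_genomes = rd("bacterial_genome.fa"),
    bacterial_cds = data.frame(
      id = names(cds_seq), species = hdr_attr("bacterial_cds.fa", "species"),
      category = hdr_attr("bacterial_cds.fa", "category"),
      seq = unname(cds_seq), stringsAsFactors = FALSE)),
    class = "pmi_refs")
}

#' Write collapsed libraries as TSV plus a samples CSV
#'
#' @param libs list of libraries (see [generate_srna_libraries()]).
#' @param dir output directory.
#' @return invisibly the directory.
#' @export
write_library_tsv <- function(libs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lib in libs) {
    write_table_meta(lib$reads,
                     file.path(dir, paste0(lib$sample_id, ".tsv")))
  }
  samples <- data.frame(
    sample_id = vapply(libs, `[[`, character(1), "sample_id"),
    timepoint_h = vapply(libs, `[[`, numeric(1), "timepoint"),
    replicate = vapply(libs, `[[`, numeric(1), "replicate"))
  write.csv(samples, file.path(dir, "samples.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}

#' Read collapsed libraries written by [write_library_tsv()]
#'
#' @param dir directory with per-sample TSV files and `samples.csv`.
#' @return list of libraries.
#' @export
read_library_tsv <- function(dir) {
  samples <- read.csv(file.path(dir, "samples.csv"), stringsAsFactors = FALSE)
  libs <- lapply(seq_len(nrow(samples)), function(i) {
    reads <- read_table_meta(file.path(dir, paste0(samples$sample_id[i], ".tsv")))
    list(sample_id = samples$sample_id[i],
         timepoint = samples$timepoint_h[i],
         replicate = samples$replicate[i],
         reads = reads)
  })
  names(libs) <- samples$sample_id
  libs
}

#' @rdname write_library_tsv
#' @param rin_table RIN data.frame.
#' @param path output CSV path.
#' @export
write_rin_csv <- function(rin_table, path) {
  df <- rin_table
  df$rin <- fmt_num(df$rin)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_library_tsv
#' @export
read_rin_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_library_tsv
#' @param deltact output of [generate_deltact_matrix()] (list with `x`,
#'   `pmi_min`).
#' @export
write_deltact_csv <- function(deltact, path) {
  df <- data.frame(animal_id = rownames(deltact$x),
                   pmi_min = fmt_num(deltact$pmi_min),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in colnames(deltact$x)) df[[j]] <- fmt_num(deltact$x[, j])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_library_tsv
#' @export
read_deltact_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  x <- as.matrix(df[, setdiff(names(df), c("animal_id", "pmi_min"))])
  rownames(x) <- df$animal_id
  list(x = x, pmi_min = df$pmi_min)
}
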