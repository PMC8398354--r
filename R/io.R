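# Reading molecule tables from the common interchange formats.

#' Read molecules from SMILES, CSV or SDF files
#'
#' * `.smi` / `.txt` — one molecule per line, `SMILES[ whitespace id]`;
#' * `.csv` — columns `id, smiles[, activity]` (any order, by name);
#' * `.sdf` — records parsed with ChemmineR; the title line is the id.
#'
#' Every record is canonicalised and its parse status recorded, so the
#' returned table doubles as a curation echo of the input file.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"smiles"`, `"csv"` or `"sdf"`.
#' @return Tibble with `id`, `smiles` (the input string), `canonical`
#'   (canonical SMILES or `NA`), `parse_ok` (logical) and, when present in
#'   the input, `activity`.
#' @export
read_molecules <- function(path, format = c("auto", "smiles", "csv", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     smi = "smiles", txt = "smiles", csv = "csv",
                     sdf = "sdf", mol = "sdf",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass `format`", call. = FALSE))
  }
  out <- switch(format,
    smiles = {
      lines <- trimws(readLines(path, warn = FALSE))
      lines <- lines[nzchar(lines)]
      parts <- strsplit(lines, "\\s+")
      tibble::tibble(
        id = vapply(seq_along(parts), function(i)
          if (length(parts[[i]]) > 1) parts[[i]][2] else sprintf("mol%03d", i),
          character(1)),
        smiles = vapply(parts, `[[`, character(1), 1)
      )
    },
    csv = {
      df <- readr::read_csv(path, show_col_types = FALSE)
      names(df) <- tolower(names(df))
      if (!"smiles" %in% names(df))
        stop("CSV must have a 'smiles' column", call. = FALSE)
      if (!"id" %in% names(df)) df$id <- sprintf("mol%03d", seq_len(nrow(df)))
      df$id <- as.character(df$id)
      keep <- intersect(c("id", "smiles", "activity"), names(df))
      df[, keep]
    },
    sdf = {
      sdfset <- ChemmineR::read.SDFset(path)
      smi <- vapply(seq_along(ChemmineR::cid(sdfset)), function(i) {
        txt <- paste(ChemmineR::sdf2str(sdfset[[i]]), collapse = "\n")
        res <- tryCatch(
          ChemmineOB::convertFormat("SDF", "CAN", paste0(txt, "\n$$$$\n")),
          error = function(e) NA_character_)
        if (is.na(res) || !nzchar(trimws(res))) NA_character_
        else strsplit(trimws(res), "[\t ]")[[1]][1]
      }, character(1))
      ids <- vapply(seq_along(ChemmineR::cid(sdfset)), function(i) {
        t <- ChemmineR::header(sdfset[[i]])[["Molecule_Name"]]
        if (is.null(t) || !nzchar(t)) sprintf("mol%03d", i) else t
      }, character(1))
      tibble::tibble(id = ids, smiles = smi)
    })
  out <- tibble::as_tibble(out)
  can <- canonical_smiles(out$smiles)
  dplyr::mutate(out, canonical = can, parse_ok = !is.na(can),
                .after = "smiles")
}
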