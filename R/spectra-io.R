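#' @importFrom data.table fread fwrite
NULL

# Canonical delimited interchange layout: one sample per row, a sample_id
# column, a named target column (concentration), and one column per grid
# point whose header is the wavenumber in cm^-1.

#' Read a spectral calibration dataset
#'
#' Reads the delimited interchange format (TSV/CSV; header row holds the
#' wavenumbers, plus a target column) or a workbook (.xlsx), converting the
#' requested sheet through the system Python's openpyxl. The spectrum length
#' is always taken from the file, never assumed.
#'
#' @param path file to read.
#' @param format `"delimited"` or `"workbook"`.
#' @param monomerLabel label of the quantified component; for workbooks this
#'   is also the default sheet to look for.
#' @param targetColumn name of the concentration column.
#' @param idColumn name of the sample-identifier column (created as
#'   `s1...sn` if absent).
#' @param sheet workbook sheet name (default: a sheet named `monomerLabel`
#'   if present, else the first sheet).
#' @param orientation `"auto"`, `"samples_in_rows"` or
#'   `"samples_in_columns"`; workbooks with wavenumbers running down the
#'   first column are transposed automatically under `"auto"`.
#' @return a [SpectralSet-class].
#' @export
readSpectra <- function(path, format = c("delimited", "workbook"),
                        monomerLabel = "", targetColumn = "concentration",
                        idColumn = "sample_id", sheet = NULL,
                        orientation = c("auto", "samples_in_rows",
                                        "samples_in_columns")) {
    format <- match.arg(format)
    orientation <- match.arg(orientation)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "workbook") {
        path <- .workbookToTsv(path, sheet = sheet,
                               preferred = monomerLabel)
    }
    df <- as.data.frame(fread(path, header = TRUE, check.names = FALSE))
    if (orientation == "samples_in_columns" ||
        (orientation == "auto" && !.looksSampleRows(df, targetColumn))) {
        df <- .transposeLayout(df, targetColumn)
    }
    nm <- names(df)
    wnCols <- which(!is.na(suppressWarnings(as.numeric(nm))))
    if (!targetColumn %in% nm)
        stop("format error: target column '", targetColumn, "' not found")
    if (length(wnCols) == 0L)
        stop("format error: no wavenumber columns found")
    for (j in c(wnCols, match(targetColumn, nm))) {
        raw <- df[[j]]
        num <- suppressWarnings(as.numeric(raw))
        bad <- which(is.na(num) & !is.na(raw) & raw != "")
        if (length(bad))
            stop(sprintf("parse error: non-numeric value '%s' at row %d, column '%s'",
                         raw[bad[1L]], bad[1L], nm[j]))
        if (anyNA(num))
            stop(sprintf("shape error: missing value at row %d, column '%s'",
                         which(is.na(num))[1L], nm[j]))
        df[[j]] <- num
    }
    ids <- if (idColumn %in% nm) as.character(df[[idColumn]])
           else paste0("s", seq_len(nrow(df)))
    SpectralSet(absorbance = as.matrix(df[wnCols]),
                wavenumbers = as.numeric(nm[wnCols]),
                concentrations = df[[targetColumn]],
                sampleIds = ids, monomerLabel = monomerLabel)
}

.looksSampleRows <- function(df, targetColumn) {
    nm <- names(df)
    targetColumn %in% nm &&
        sum(!is.na(suppressWarnings(as.numeric(nm)))) >= 2L
}

# Layout with wavenumbers down the first column and one column per sample
# (target stored in a row labelled with the target-column name).
.transposeLayout <- function(df, targetColumn) {
    lab <- as.character(df[[1L]])
    tRow <- which(lab == targetColumn)
    if (length(tRow) != 1L)
        stop("format error: target column '", targetColumn,
             "' not found in either orientation")
    out <- as.data.frame(t(as.matrix(df[-tRow, -1L, drop = FALSE])),
                         stringsAsFactors = FALSE)
    names(out) <- lab[-tRow]
    out[[targetColumn]] <- as.numeric(t(df[tRow, -1L, drop = FALSE]))
    out$sample_id <- names(df)[-1L]
    out
}

.workbookToTsv <- function(path, sheet = NULL, preferred = "") {
    out <- tempfile(fileext = ".tsv")
    script <- c(
        "import sys, csv, openpyxl",
        "src, dst, sheet, pref = sys.argv[1:5]",
        "wb = openpyxl.load_workbook(src, read_only=True, data_only=True)",
        "names = wb.sheetnames",
        "name = sheet if sheet in names else (pref if pref in names else names[0])",
        "ws = wb[name]",
        "with open(dst, 'w', newline='') as fh:",
        "    w = csv.writer(fh, delimiter='\\t')",
        "    for row in ws.iter_rows(values_only=True):",
        "        w.writerow(['' if v is None else v for v in row])")
    sf <- tempfile(fileext = ".py")
    writeLines(script, sf)
    status <- system2("python", c(sf, shQuote(path), shQuote(out),
                                  shQuote(if (is.null(sheet)) "" else sheet),
                                  shQuote(preferred)),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L || !file.exists(out))
        stop("workbook conversion failed (is python with openpyxl available?)")
    out
}

#' Write a spectral dataset in the delimited interchange format
#'
#' @param ds a [SpectralSet-class].
#' @param path output file (UTF-8, '.' decimal separator).
#' @param sep field separator (tab by default).
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(ds, path, sep = "\t") {
    m <- spectraMatrix(ds)
    df <- data.frame(sample_id = sampleIds(ds),
                     concentration = concentrations(ds),
                     check.names = FALSE)
    sp <- as.data.frame(m, check.names = FALSE)
    names(sp) <- format(wavenumbers(ds), trim = TRUE, digits = 15)
    fwrite(cbind(df, sp), path, sep = sep)
    invisible(path)
}

#' Resample a spectrum onto a target grid by bin averaging
#'
#' Each output value is the mean of source points whose wavenumber falls in
#' the target bin; bin edges sit at midpoints between consecutive target
#' grid values (outer bins extend by half the local spacing). Empty bins,
#' which only arise when the target grid is finer than the source, are
#' filled by linear interpolation.
#'
#' @param spec a [Spectrum-class].
#' @param targetGrid wavenumber vector inside the source grid's span.
#' @return a [Spectrum-class] on `targetGrid`.
#' @export
resampleToGrid <- function(spec, targetGrid) {
    src <- wavenumbers(spec)
    if (min(targetGrid) < min(src) || max(targetGrid) > max(src))
        stop("range error: target grid extends beyond the source span")
    o <- order(targetGrid)
    tg <- targetGrid[o]
    a <- absorbance(spec)
    if (length(tg) == 1L) {
        vals <- mean(a)
    } else {
        edges <- c(tg[1L] - diff(tg[1:2]) / 2,
                   tg[-length(tg)] + diff(tg) / 2,
                   tg[length(tg)] + diff(tg)[length(tg) - 1L] / 2)
        bin <- cut(src, breaks = edges, include.lowest = TRUE, labels = FALSE)
        sums <- tapply(a[!is.na(bin)], bin[!is.na(bin)], mean)
        vals <- rep(NA_real_, length(tg))
        vals[as.integer(names(sums))] <- as.numeric(sums)
        if (anyNA(vals)) {
            filled <- stats::approx(src, a, xout = tg[is.na(vals)],
                                    rule = 2)$y
            vals[is.na(vals)] <- filled
        }
    }
    out <- vals
    out[o] <- vals   # restore original target order
    Spectrum(out, targetGrid, sampleIds(spec))
}

#' Summary statistics of a dataset's concentration target
#'
#' Reports the sample count and the mean, sample standard deviation
#' (n-1 denominator), maximum and minimum of the concentration vector at
#' full precision; rounding is left to presentation.
#'
#' @param ds a [SpectralSet-class].
#' @return data.frame with columns `monomer`, `n`, `mean`, `sd`, `max`, `min`.
#' @export
summarizeDataset <- function(ds) {
    y <- concentrations(ds)
    if (length(y) == 0L) stop("empty dataset: no samples to summarise")
    data.frame(monomer = monomerLabel(ds), n = length(y),
               mean = mean(y), sd = if (length(y) > 1L) sd(y) else 0,
               max = max(y), min = min(y))
}
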