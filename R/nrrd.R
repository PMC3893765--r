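# Minimal NRRD0004 reader/writer for 3D scalar grids. Supports attached
# data in raw, gzip and ascii encodings; spacing/origin carried as
# "space directions" / "space origin" (axis-aligned only) or "spacings".

.nrrd_types <- list(
    "double" = list(what = "double", size = 8L),
    "float"  = list(what = "double", size = 4L),
    "int"    = list(what = "integer", size = 4L),
    "signed int" = list(what = "integer", size = 4L),
    "uint"   = list(what = "integer", size = 4L),
    "short"  = list(what = "integer", size = 2L),
    "signed short" = list(what = "integer", size = 2L),
    "ushort" = list(what = "integer", size = 2L),
    "uchar"  = list(what = "integer", size = 1L),
    "unsigned char" = list(what = "integer", size = 1L))

.parse_nrrd_vectors <- function(s) {
    # "(1,0,0) (0,1,0) (0,0,2.5)" -> list of numeric vectors; "none" -> NULL
    m <- gregexpr("\\(([^)]*)\\)", s)[[1]]
    if (m[1] == -1) return(NULL)
    lapply(regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]], function(v) {
        as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
    })
}

.read_nrrd <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    magic <- readLines(con, n = 1L)
    if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path)
    fields <- list()
    repeat {
        line <- readLines(con, n = 1L)
        if (length(line) == 0L) stop("truncated NRRD header")
        if (line == "") break
        if (grepl("^#", line)) next
        kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
        if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
    }
    dimn <- as.integer(fields[["dimension"]])
    if (is.na(dimn) || dimn != 3L)
        stop("non-3D data: NRRD dimension is ", fields[["dimension"]])
    sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
    if (length(sizes) != 3L || any(sizes < 1L)) stop("bad NRRD sizes field")

    spacing <- NULL
    origin <- c(0, 0, 0)
    if (!is.null(fields[["space directions"]])) {
        dirs <- .parse_nrrd_vectors(fields[["space directions"]])
        if (length(dirs) != 3L) stop("bad space directions")
        for (a in 1:3) {
            offaxis <- dirs[[a]][-a]
            if (any(abs(offaxis) > 1e-9 * max(abs(dirs[[a]]))))
                stop("oblique space directions are not supported")
        }
        spacing <- vapply(1:3, function(a) abs(dirs[[a]][a]), numeric(1))
    } else if (!is.null(fields[["spacings"]])) {
        spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
    }
    if (is.null(spacing) || length(spacing) != 3L || any(is.na(spacing)))
        stop("NRRD header carries no voxel spacing ",
             "(need 'space directions' or 'spacings')")
    if (any(spacing <= 0)) stop("non-positive spacing in NRRD header")
    if (!is.null(fields[["space origin"]])) {
        o <- .parse_nrrd_vectors(fields[["space origin"]])
        if (length(o) == 1L && length(o[[1]]) == 3L) origin <- o[[1]]
    }

    type <- tolower(fields[["type"]])
    enc <- tolower(fields[["encoding"]])
    n <- prod(sizes)
    if (enc == "ascii" || enc == "text" || enc == "txt") {
        txt <- readLines(con)
        vals <- as.numeric(scan(text = paste(txt, collapse = " "),
                                quiet = TRUE))
        if (length(vals) != n) stop("ascii NRRD data length mismatch")
    } else if (enc %in% c("raw", "gzip", "gz")) {
        ti <- .nrrd_types[[type]]
        if (is.null(ti)) stop("unsupported NRRD type: ", type)
        endian <- fields[["endian"]]
        endian <- if (is.null(endian)) "little" else tolower(endian)
        dcon <- con
        if (enc != "raw") {
            blob <- readBin(con, "raw", n = file.size(path))
            dcon <- gzcon(rawConnection(blob))
            on.exit(close(dcon), add = TRUE)
        }
        signed <- !grepl("^u", type)
        vals <- readBin(dcon, ti$what, n = n, size = ti$size,
                        signed = if (ti$size < 4L) signed else TRUE,
                        endian = endian)
        if (length(vals) != n) stop("NRRD data shorter than sizes imply")
        vals <- as.numeric(vals)
    } else {
        stop("unsupported NRRD encoding: ", enc)
    }
    voxelGrid3D(array(vals, dim = sizes), spacing = spacing, origin = origin)
}

.write_nrrd <- function(grid, path, encoding = c("raw", "ascii")) {
    encoding <- match.arg(encoding)
    d <- dim(grid@values)
    sp <- grid@spacing
    o <- grid@origin
    hdr <- c(
        "NRRD0004",
        "# srstcp voxel grid",
        "type: double",
        "dimension: 3",
        "space dimension: 3",
        sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
        sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                sp[1], sp[2], sp[3]),
        sprintf("space origin: (%.17g,%.17g,%.17g)", o[1], o[2], o[3]),
        "kinds: domain domain domain",
        if (encoding == "raw") "endian: little",
        sprintf("encoding: %s", encoding),
        "")
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeLines(hdr, con, sep = "\n")
    if (encoding == "raw") {
        writeBin(as.numeric(grid@values), con, size = 8L, endian = "little")
    } else {
        writeLines(format(as.numeric(grid@values), digits = 17,
                          scientific = TRUE, trim = TRUE), con, sep = "\n")
    }
    invisible(path)
}
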