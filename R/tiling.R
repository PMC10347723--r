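#' Segment a genome into fixed-width non-overlapping tiles
#'
#' Splits every chromosome into consecutive `tile_width`-bp tiles
#' `[i*w, (i+1)*w)`; a trailing partial tile shorter than `tile_width` is
#' dropped. Tiles receive dense integer ids (0-based) ordered by
#' chromosome (input order) and then start coordinate, giving a stable
#' bijection between `(chrom, start)` and tile id.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @param tile_width tile width in bp (default 1000).
#' @return An object of class `tiled_genome`: a list with `chrom_sizes`,
#'   `tile_width` and a `data.table` `tiles` with columns
#'   `id`, `chrom`, `start`, `end`.
#' @examples
#' tg <- tile_genome(c(chr1 = 10500), tile_width = 1000)
#' nrow(tg$tiles)  # 10: trailing 500 bp dropped
#' @export
tile_genome <- function(chrom_sizes, tile_width = 1000L) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  tile_width <- as.integer(tile_width)
  if (tile_width < 1L) stop("tile_width must be >= 1")
  pieces <- lapply(names(chrom_sizes), function(ch) {
    n <- floor(chrom_sizes[[ch]] / tile_width)
    if (n < 1) {
      warning("chromosome ", ch, " shorter than one tile; zero tiles emitted")
      return(NULL)
    }
    data.table::data.table(
      chrom = ch,
      start = as.integer(seq_len(n) - 1L) * tile_width
    )
  })
  tiles <- data.table::rbindlist(pieces)
  if (nrow(tiles) == 0L) stop("no tiles: all chromosomes shorter than tile_width")
  tiles[, `:=`(id = seq_len(.N) - 1L, end = start + tile_width)]
  data.table::setcolorder(tiles, c("id", "chrom", "start", "end"))
  structure(
    list(chrom_sizes = chrom_sizes, tile_width = tile_width, tiles = tiles[]),
    class = "tiled_genome"
  )
}

#' @export
print.tiled_genome <- function(x, ...) {
  cat("tiled_genome:", length(x$chrom_sizes), "chromosome(s),",
      nrow(x$tiles), "tiles of", x$tile_width, "bp\n")
  invisible(x)
}

#' Map genomic positions to tile ids
#'
#' Positions falling in a dropped trailing partial tile (or past the
#' chromosome end) are returned as `NA` with a warning.
#'
#' @param tg a [tile_genome()] object.
#' @param chrom,pos equal-length vectors of chromosome names and 0-based
#'   positions.
#' @return integer vector of tile ids (`NA` where unmappable).
#' @export
tile_id_at <- function(tg, chrom, pos) {
  first <- tg$tiles[, .(first_id = id[1L], n = .N), by = chrom]
  idx <- match(chrom, first$chrom)
  k <- floor(pos / tg$tile_width)
  id <- first$first_id[idx] + as.integer(k)
  bad <- is.na(idx) | k >= first$n[idx] | pos < 0
  if (any(bad)) {
    warning(sum(bad), " position(s) outside the tiled region discarded")
    id[bad] <- NA_integer_
  }
  id
}

#' Look up tile coordinates by id
#' @param tg a [tile_genome()] object.
#' @param id integer tile ids.
#' @return `data.table` with `id`, `chrom`, `start`, `end`.
#' @export
tile_coords <- function(tg, id) {
  out <- tg$tiles[match(id, tg$tiles$id)]
  if (anyNA(out$chrom)) stop("unknown tile id(s)")
  out
}
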