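# Plain-text artifact formats. Everything is tab-separated with a header
# line, preceded by '#' provenance comments (package version, seed, config
# hash). Numbers are written with 17 significant digits so a write -> read ->
# write cycle is byte-identical and values survive the round trip exactly.
# Ids and receptor slots are 0-based in files, 1-based in memory.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[x == round(x) & abs(x) < 2^31] <- sprintf("%d", as.integer(x[x == round(x) & abs(x) < 2^31]))
  out
}

provenance_header <- function(seed = NA, extra = character(0)) {
  c(sprintf("# granlif %s", as.character(utils::packageVersion("granlif"))),
    sprintf("# seed=%s", format(seed)),
    extra)
}

#' Hash of a configuration object
#'
#' MD5 of the deparsed object; used in provenance headers so outputs can be
#' traced back to the exact configuration that produced them.
#'
#' @param x any R object.
#' @return A 32-character hex string.
#' @export
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

write_tsv <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col)) fmt_num(col) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

read_tsv <- function(path, colClasses) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = colClasses, stringsAsFactors = FALSE)
}

#' Write a network to plain-text files
#'
#' Two tab-separated files are produced in `dir`: `positions.tsv`
#' (`pop, id, x, y, z`, um) and `edges.tsv`
#' (`src_pop, src_id, dst_pop, dst_id, receptor_slot, delay_ms`). Mossy-fiber
#' membership is stored as `mf -> glo` rows; granule-to-Golgi pathway tags are
#' encoded in `src_pop` (`grc_aa` / `grc_pf`). Ids and slots are 0-based in
#' the files. The writer/reader pair round-trips losslessly.
#'
#' @param net a `gl_network`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(sprintf("# volume=%s,%s,%s", fmt_num(net$volume$x),
                    fmt_num(net$volume$y), fmt_num(net$volume$z)),
            sprintf("# densities=%s,%s,%s,%s",
                    fmt_num(net$densities$rho_grc), fmt_num(net$densities$rho_goc),
                    fmt_num(net$densities$rho_glo),
                    fmt_num(net$densities$mf_per_glo_ratio)),
            sprintf("# config_hash=%s", config_hash(net$rules)))
  hdr <- provenance_header(net$seed, meta)
  pos <- do.call(rbind, lapply(c("goc", "grc", "glo"), function(p) {
    m <- net$positions[[p]]
    data.frame(pop = p, id = seq_len(nrow(m)) - 1L,
               x = m[, 1], y = m[, 2], z = m[, 3])
  }))
  write_tsv(pos, file.path(dir, "positions.tsv"), hdr)
  z <- function(i) as.integer(i) - 1L
  # non-receptor rows (mf->glo membership, goc->glo axon) carry slot/delay 0
  ed <- rbind(
    data.frame(src_pop = "mf", src_id = z(net$glo_to_mf), dst_pop = "glo",
               dst_id = z(seq_along(net$glo_to_mf)), receptor_slot = 0L,
               delay_ms = 0),
    data.frame(src_pop = "grc", src_id = z(net$edges_grc_glo$grc),
               dst_pop = "glo", dst_id = z(net$edges_grc_glo$glo),
               receptor_slot = z(net$edges_grc_glo$slot),
               delay_ms = net$edges_grc_glo$delay_ms),
    data.frame(src_pop = "glo", src_id = z(net$edges_glo_goc_dend$glo),
               dst_pop = "goc", dst_id = z(net$edges_glo_goc_dend$goc),
               receptor_slot = z(net$edges_glo_goc_dend$slot),
               delay_ms = net$edges_glo_goc_dend$delay_ms),
    data.frame(src_pop = "goc", src_id = z(net$edges_goc_glo_axon$goc),
               dst_pop = "glo", dst_id = z(net$edges_goc_glo_axon$glo),
               receptor_slot = 0L, delay_ms = 0),
    data.frame(src_pop = "goc", src_id = z(net$edges_goc_grc_inh$goc),
               dst_pop = "grc", dst_id = z(net$edges_goc_grc_inh$grc),
               receptor_slot = z(net$edges_goc_grc_inh$slot),
               delay_ms = net$edges_goc_grc_inh$delay_ms),
    data.frame(src_pop = paste0("grc_", net$edges_grc_goc_exc$pathway),
               src_id = z(net$edges_grc_goc_exc$grc), dst_pop = "goc",
               dst_id = z(net$edges_grc_goc_exc$goc),
               receptor_slot = z(net$edges_grc_goc_exc$slot),
               delay_ms = net$edges_grc_goc_exc$delay_ms)
  )
  write_tsv(ed, file.path(dir, "edges.tsv"), hdr)
  invisible(dir)
}

#' Read a network written by [write_network()]
#'
#' Reconstructs the `gl_network` (positions, mossy-fiber mapping and all five
#' edge tables) and recomputes its audit. Densities, volume and seed are
#' restored from the provenance header.
#'
#' @param dir directory containing `positions.tsv` and `edges.tsv`.
#' @param rules a [rule_config()]; the rule set is not serialized, so supply
#'   the one used at build time if it was not the default.
#' @return A `gl_network`.
#' @export
read_network <- function(dir, rules = rule_config()) {
  pos_path <- file.path(dir, "positions.tsv")
  hdr <- grep("^#", readLines(pos_path, n = 10), value = TRUE)
  get_meta <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    strsplit(sub(paste0("^# ", key, "="), "", ln[1]), ",")[[1]]
  }
  vol <- as.numeric(get_meta("volume"))
  den <- as.numeric(get_meta("densities"))
  seed <- suppressWarnings(as.integer(get_meta("seed")))
  pos <- read_tsv(pos_path, c("character", "integer", rep("numeric", 3)))
  ed <- read_tsv(file.path(dir, "edges.tsv"),
                 c("character", "integer", "character", "integer",
                   "integer", "numeric"))
  positions <- lapply(split(pos, pos$pop), function(d) {
    m <- as.matrix(d[order(d$id), c("x", "y", "z")])
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    m
  })[c("goc", "grc", "glo")]
  pick <- function(sp, dp) ed[ed$src_pop == sp & ed$dst_pop == dp, ]
  mf <- pick("mf", "glo")
  glo_to_mf <- integer(nrow(positions$glo))
  glo_to_mf[mf$dst_id + 1L] <- mf$src_id + 1L
  gg <- pick("grc", "glo")
  gd <- pick("glo", "goc")
  axn <- pick("goc", "glo")
  inh <- pick("goc", "grc")
  ge <- ed[ed$src_pop %in% c("grc_aa", "grc_pf") & ed$dst_pop == "goc", ]
  exc <- data.frame(grc = ge$src_id + 1L, goc = ge$dst_id + 1L,
                    slot = ge$receptor_slot + 1L,
                    pathway = sub("^grc_", "", ge$src_pop),
                    delay_ms = ge$delay_ms)
  rownames(exc) <- NULL
  volume <- volume_spec(vol[1], vol[2], vol[3])
  densities <- density_config(den[1], den[2], den[3], den[4])
  net <- structure(list(
    positions = positions,
    glo_to_mf = glo_to_mf,
    edges_grc_glo = data.frame(grc = gg$src_id + 1L, glo = gg$dst_id + 1L,
                               slot = gg$receptor_slot + 1L,
                               delay_ms = gg$delay_ms),
    edges_glo_goc_dend = data.frame(glo = gd$src_id + 1L, goc = gd$dst_id + 1L,
                                    slot = gd$receptor_slot + 1L,
                                    delay_ms = gd$delay_ms),
    edges_goc_glo_axon = data.frame(goc = axn$src_id + 1L, glo = axn$dst_id + 1L),
    edges_goc_grc_inh = data.frame(goc = inh$src_id + 1L, grc = inh$dst_id + 1L,
                                   slot = inh$receptor_slot + 1L,
                                   delay_ms = inh$delay_ms),
    edges_grc_goc_exc = exc,
    counts = list(n_goc = nrow(positions$goc), n_grc = nrow(positions$grc),
                  n_glo = nrow(positions$glo),
                  n_mf = length(unique(glo_to_mf))),
    volume = volume, densities = densities, rules = rules, seed = seed,
    build_log = list(grc_dendrites = list(n_relaxed = NA_integer_,
                                          max_radius_used = NA_real_,
                                          n_overflow = NA_integer_))
  ), class = "gl_network")
  net$audit <- audit_network(net)
  net
}

#' Write / read a spike raster
#'
#' Tab-separated `time_ms, population, neuron_id` (0-based ids), ascending in
#' time, with a provenance header.
#'
#' @param sim a `gl_sim` from [run_simulation()], or a raster data.frame.
#' @param path output file.
#' @param seed seed to record in the header.
#' @return `path` ([write_raster()]) or the raster data.frame
#'   ([read_raster()]), with 1-based `neuron_id`.
#' @export
write_raster <- function(sim, path, seed = NULL) {
  raster <- if (inherits(sim, "gl_sim")) sim$raster else sim
  if (is.null(seed) && inherits(sim, "gl_sim")) seed <- sim$meta$seed
  if (is.null(seed)) seed <- attr(raster, "seed")
  out <- data.frame(time_ms = raster$time_ms, population = raster$population,
                    neuron_id = as.integer(raster$neuron_id) - 1L)
  write_tsv(out, path, provenance_header(seed %||% NA))
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  hdr <- grep("^#", readLines(path, n = 5), value = TRUE)
  seed_ln <- grep("^# seed=", hdr, value = TRUE)
  d <- read_tsv(path, c("numeric", "character", "integer"))
  d$neuron_id <- d$neuron_id + 1L
  if (length(seed_ln))
    attr(d, "seed") <- suppressWarnings(as.integer(sub("^# seed=", "", seed_ln[1])))
  d
}

#' Write / read membrane traces
#'
#' Long tab-separated format `time_ms, population, neuron_id, vm_mv` with a
#' provenance header.
#'
#' @param sim a `gl_sim` with recorded traces.
#' @param path output file.
#' @return `path` ([write_traces()]) or a data.frame ([read_traces()]).
#' @export
write_traces <- function(sim, path) {
  stopifnot(inherits(sim, "gl_sim"))
  rows <- list()
  for (p in names(sim$traces)) {
    m <- sim$traces[[p]]
    tt <- attr(m, "time_ms")
    for (j in seq_len(ncol(m))) {
      rows[[length(rows) + 1L]] <-
        data.frame(time_ms = tt, population = p,
                   neuron_id = as.integer(colnames(m)[j]) - 1L,
                   vm_mv = m[, j])
    }
  }
  d <- if (length(rows)) do.call(rbind, rows)
  else data.frame(time_ms = numeric(0), population = character(0),
                  neuron_id = integer(0), vm_mv = numeric(0))
  write_tsv(d, path, provenance_header(sim$meta$seed %||% NA))
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  d <- read_tsv(path, c("numeric", "character", "integer", "numeric"))
  d$neuron_id <- d$neuron_id + 1L
  d
}

#' Write an audit report
#'
#' @param audit a `gl_audit`.
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_audit <- function(audit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sink(con)
  print(audit)
  sink()
  invisible(path)
}
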