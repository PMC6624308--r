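#' @title Taxonomy with strain-level genome nodes
#'
#' @description
#' Loads an NCBI-dialect taxonomy (`nodes.dmp` / `names.dmp` column layout,
#' `"|"`-delimited) together with a two-column genome-to-taxon map and
#' extends it with strain-level leaf nodes so that every mappable genome is
#' attached to exactly one node:
#'
#' * a taxon mapped by a single genome and without children keeps the genome
#'   attached directly (its strain- and species-level projections coincide);
#' * a taxon with children, or mapped by more than one genome, receives one
#'   fresh synthetic strain leaf per genome.
#'
#' Synthetic node ids are allocated deterministically from a reserved high
#' range (from `1e8` upward) and recorded in the `$synthetic` sidecar table
#' so repeated runs are reproducible.
#'
#' @param nodes_table Path to a nodes table (`taxon_id | parent_id | rank |
#'   ...`) or a data.frame with columns `taxon_id`, `parent_id`, `rank`.
#' @param names_table Path to a names table (`taxon_id | name | unique |
#'   class |`; scientific names preferred) or a data.frame with columns
#'   `taxon_id`, `name`. May be `NULL` (names default to the taxon id).
#' @param genome_map Path to a two-column TSV (`genome_id <tab> taxon_id`,
#'   no header) or a data.frame with those columns. May be `NULL` for a
#'   genome-less taxonomy.
#' @return An object of class `taxonomy`: a list with `nodes` (data.table:
#'   `taxon_id`, `parent_id`, `rank`, `name`, `genome_id`), `synthetic`
#'   (sidecar data.table of inserted strain nodes) and internal lookup
#'   tables.
#' @examples
#' nodes <- data.frame(taxon_id = c(1L, 2L, 3L), parent_id = c(1L, 1L, 2L),
#'                     rank = c("root", "genus", "species"))
#' gm <- data.frame(genome_id = c("g1", "g2"), taxon_id = c(3L, 3L))
#' tax <- load_taxonomy(nodes, NULL, gm)
#' tax$synthetic  # two synthetic strain leaves under taxon 3
#' @export
load_taxonomy <- function(nodes_table, names_table = NULL, genome_map = NULL) {
  nodes <- if (is.character(nodes_table)) read_dmp(nodes_table, 3L,
    c("taxon_id", "parent_id", "rank")) else as.data.table(nodes_table)
  nodes <- nodes[, .(taxon_id = as.integer(taxon_id),
                     parent_id = as.integer(parent_id),
                     rank = as.character(rank))]
  if (anyDuplicated(nodes$taxon_id))
    stop("duplicate taxon_id in nodes table: ",
         paste(unique(nodes$taxon_id[duplicated(nodes$taxon_id)]),
               collapse = ", "))
  if (any(nodes$taxon_id == 0L))
    stop("taxon_id 0 is reserved for 'unassigned' and cannot be a tree node")
  miss <- setdiff(nodes$parent_id, nodes$taxon_id)
  if (length(miss))
    stop("parent taxon not present in nodes table: ",
         paste(miss, collapse = ", "))

  if (!is.null(names_table)) {
    nm <- if (is.character(names_table)) read_dmp(names_table, 4L,
      c("taxon_id", "name", "unique_name", "name_class")) else {
        x <- as.data.table(names_table)
        if (!"name_class" %in% names(x)) x[, name_class := "scientific name"]
        if (!"unique_name" %in% names(x)) x[, unique_name := ""]
        x
      }
    nm[, taxon_id := as.integer(taxon_id)]
    sci <- nm[name_class == "scientific name" | !any(nm$name_class ==
              "scientific name")]
    sci <- sci[!duplicated(taxon_id)]
    nodes[sci, name := i.name, on = "taxon_id"]
  }
  if (!"name" %in% names(nodes)) nodes[, name := NA_character_]
  nodes[is.na(name), name := paste0("taxon_", taxon_id)]
  nodes[, genome_id := NA_character_]

  validate_tree(nodes)

  synthetic <- data.table(taxon_id = integer(), parent_id = integer(),
                          genome_id = character(), name = character())
  if (!is.null(genome_map)) {
    gm <- if (is.character(genome_map)) {
      fread(genome_map, header = FALSE, sep = "\t",
            col.names = c("genome_id", "taxon_id"))
    } else as.data.table(genome_map)
    gm <- gm[, .(genome_id = as.character(genome_id),
                 taxon_id = as.integer(taxon_id))]
    if (anyDuplicated(gm$genome_id))
      stop("duplicate genome_id in genome map")
    unk <- setdiff(gm$taxon_id, nodes$taxon_id)
    if (length(unk))
      stop("genome mapped to unknown taxon: ", paste(unk, collapse = ", "))
    has_children <- unique(nodes$parent_id[nodes$parent_id != nodes$taxon_id])
    n_per_taxon <- gm[, .N, by = taxon_id]
    next_id <- 100000000L
    setorder(gm, genome_id)
    for (i in seq_len(nrow(gm))) {
      tid <- gm$taxon_id[i]
      gid <- gm$genome_id[i]
      direct <- n_per_taxon[taxon_id == tid, N] == 1L &&
        !(tid %in% has_children)
      if (direct) {
        nodes[taxon_id == tid, genome_id := gid]
      } else {
        pname <- nodes[taxon_id == tid, name]
        newnode <- data.table(taxon_id = next_id, parent_id = tid,
                              rank = "strain",
                              name = paste0(pname, " strain ", gid),
                              genome_id = gid)
        nodes <- rbind(nodes, newnode)
        synthetic <- rbind(synthetic,
          data.table(taxon_id = next_id, parent_id = tid, genome_id = gid,
                     name = newnode$name))
        next_id <- next_id + 1L
      }
    }
  }

  new_taxonomy(nodes, synthetic)
}

new_taxonomy <- function(nodes, synthetic) {
  setkey(nodes, taxon_id)
  parent <- setNames(nodes$parent_id, nodes$taxon_id)
  rank <- setNames(nodes$rank, nodes$taxon_id)
  genome <- setNames(nodes$genome_id, nodes$taxon_id)
  taxon_of_genome <- setNames(nodes$taxon_id[!is.na(nodes$genome_id)],
                              nodes$genome_id[!is.na(nodes$genome_id)])
  structure(list(nodes = nodes, synthetic = synthetic, parent = parent,
                 rank = rank, genome = genome,
                 taxon_of_genome = taxon_of_genome),
            class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> ", nrow(x$nodes), " nodes (",
      nrow(x$synthetic), " synthetic strain nodes), ",
      sum(!is.na(x$nodes$genome_id)), " mappable genomes\n", sep = "")
  invisible(x)
}

read_dmp <- function(path, n_fields, col_names) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(sub("\t\\|$", "", lines), "\t\\|\t")
  bad <- lengths(parts) < n_fields
  if (any(bad)) stop("malformed dmp line(s) in ", path, ": ",
                     paste(which(bad)[1], collapse = ", "))
  dt <- as.data.table(do.call(rbind, lapply(parts, `[`, seq_len(n_fields))))
  setnames(dt, col_names)
  dt
}

validate_tree <- function(nodes) {
  parent <- setNames(nodes$parent_id, nodes$taxon_id)
  roots <- nodes$taxon_id[nodes$taxon_id == nodes$parent_id]
  if (length(roots) != 1L)
    stop("tree must have exactly one root (node with parent_id == taxon_id); ",
         "found ", length(roots))
  # cycle check: every node must reach the root
  n <- nrow(nodes)
  for (t in nodes$taxon_id) {
    cur <- t
    for (step in seq_len(n + 1L)) {
      p <- parent[[as.character(cur)]]
      if (p == cur) break
      cur <- p
      if (step > n) stop("cycle detected in taxonomy at taxon ", t)
    }
    if (parent[[as.character(cur)]] != cur)
      stop("cycle detected in taxonomy at taxon ", t)
  }
  invisible(TRUE)
}

# Named rank ladder, most specific first. "no rank" and other labels are
# unnamed and skipped when projecting.
tax_ranks <- function() {
  c("strain", "species", "genus", "family", "order", "class", "phylum",
    "kingdom", "superkingdom", "root")
}

rank_index <- function(r) match(r, tax_ranks())

#' Project a taxonomic assignment to a named level
#'
#' Converts an assignment (a taxon id, or 0 meaning "unassigned") to a given
#' taxonomic level: the node itself if it already has that rank; its l-level
#' ancestor if it is more specific; 0 if it is less specific than the level,
#' if the ancestral path lacks that rank entirely, or if the input is 0. For
#' `level = "strain"` the node is returned iff a mappable genome is attached
#' to it, and 0 otherwise. Nodes with unnamed ranks ("no rank") are walked
#' through transparently.
#'
#' @param taxonomy A [load_taxonomy()] object.
#' @param a Integer vector of taxon ids (0 allowed).
#' @param level One of `r toString(tax_ranks())`.
#' @return Integer vector: projected taxon ids (0 = no projection).
#' @export
to_level <- function(taxonomy, a, level) {
  if (!level %in% tax_ranks())
    stop("unknown taxonomic rank: ", level)
  a <- as.integer(a)
  bad <- a != 0L & !(a %in% taxonomy$nodes$taxon_id)
  if (any(bad)) stop("unknown taxon id: ", paste(a[bad], collapse = ", "))
  vapply(a, function(x) to_level1(taxonomy, x, level), integer(1))
}

to_level1 <- function(taxonomy, a, level) {
  if (a == 0L) return(0L)
  if (level == "strain")
    return(if (!is.na(taxonomy$genome[[as.character(a)]])) a else 0L)
  target <- rank_index(level)
  cur <- a
  repeat {
    key <- as.character(cur)
    ri <- rank_index(taxonomy$rank[[key]])
    if (!is.na(ri)) {
      if (ri == target) return(cur)
      if (ri > target) return(0L)  # already less specific than `level`
    }
    p <- taxonomy$parent[[key]]
    if (p == cur) return(0L)  # reached root without finding `level`
    cur <- p
  }
}

#' Lowest common ancestor of two taxa
#'
#' @param taxonomy A [load_taxonomy()] object.
#' @param a,b Valid taxon ids.
#' @return The deepest node ancestral to (or equal to) both.
#' @export
lca <- function(taxonomy, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  for (x in c(a, b))
    if (!x %in% taxonomy$nodes$taxon_id) stop("unknown taxon id: ", x)
  anc <- ancestors(taxonomy, a)
  cur <- b
  repeat {
    if (cur %in% anc) return(cur)
    p <- taxonomy$parent[[as.character(cur)]]
    if (p == cur) return(cur)
    cur <- p
  }
}

ancestors <- function(taxonomy, a) {
  out <- a
  cur <- a
  repeat {
    p <- taxonomy$parent[[as.character(cur)]]
    if (p == cur) break
    out <- c(out, p)
    cur <- p
  }
  out
}

#' Taxon node attached to each genome
#'
#' @param taxonomy A [load_taxonomy()] object.
#' @param genome_ids Character vector of genome ids.
#' @return Integer vector of taxon ids (the strain-level node of each
#'   genome).
#' @export
taxon_of_genome <- function(taxonomy, genome_ids) {
  out <- taxonomy$taxon_of_genome[as.character(genome_ids)]
  if (anyNA(out))
    stop("genome(s) not attached to the taxonomy: ",
         paste(genome_ids[is.na(out)], collapse = ", "))
  unname(out)
}

#' Write taxonomy tables in the NCBI dmp dialect
#'
#' Emits `nodes.dmp`, `names.dmp`, a `genome_map.tsv` for attached genomes,
#' and a `synthetic_nodes.tsv` sidecar listing inserted strain nodes.
#'
#' @param taxonomy A [load_taxonomy()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_taxonomy_tables <- function(taxonomy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nd <- taxonomy$nodes
  nodes_path <- file.path(dir, "nodes.dmp")
  names_path <- file.path(dir, "names.dmp")
  writeLines(paste0(nd$taxon_id, "\t|\t", nd$parent_id, "\t|\t", nd$rank,
                    "\t|"), nodes_path)
  writeLines(paste0(nd$taxon_id, "\t|\t", nd$name, "\t|\t\t|\t",
                    "scientific name\t|"), names_path)
  gm <- nd[!is.na(genome_id), .(genome_id, taxon_id)]
  gm_path <- file.path(dir, "genome_map.tsv")
  fwrite(gm, gm_path, sep = "\t", col.names = FALSE)
  syn_path <- file.path(dir, "synthetic_nodes.tsv")
  fwrite(taxonomy$synthetic, syn_path, sep = "\t")
  invisible(c(nodes = nodes_path, names = names_path, genome_map = gm_path,
              synthetic = syn_path))
}
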