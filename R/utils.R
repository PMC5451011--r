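# Internal helpers shared across modules.

# Union-find over integer indices 1..n: merge every element of each set with
# the first element of that set. `sets` is a list of integer index vectors
# into 1..n; returns component labels (root index per element).
uf_components <- function(n, sets) {
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    # path compression
    while (parent[i] != root) {
      nxt <- parent[i]
      parent[i] <<- root
      i <- nxt
    }
    root
  }
  for (s in sets) {
    if (length(s) < 2L) next
    r0 <- find(s[1L])
    for (i in s[-1L]) {
      r <- find(i)
      if (r != r0) {
        parent[r] <- r0
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Split a gene annotation string on the conventional separators.
split_genes <- function(x) {
  out <- lapply(x, function(g) {
    if (is.na(g) || !nzchar(trimws(g))) return(character())
    parts <- trimws(strsplit(g, "[;,|]")[[1L]])
    parts[nzchar(parts)]
  })
  out
}

genes_to_string <- function(genes) {
  vapply(genes, function(g) paste(g, collapse = ";"), character(1))
}

# Case-insensitive non-empty intersection of two gene-symbol vectors.
genes_overlap <- function(a, b) {
  length(a) > 0L && length(b) > 0L &&
    length(intersect(toupper(a), toupper(b))) > 0L
}

assert_inherits <- function(x, class, arg = deparse(substitute(x))) {
  if (!inherits(x, class)) {
    abort(sprintf("`%s` must be a <%s> object, got <%s>.",
                  arg, class, class(x)[1]))
  }
  invisible(x)
}

match_mode <- function(mode) {
  mode <- gsub("-", "_", tolower(mode))
  match.arg(mode, c("all", "top_gene", "top_identifier"))
}
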