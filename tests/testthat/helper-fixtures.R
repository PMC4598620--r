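# Hand-built fixture trees (constructed through the internal constructor;
# tests run in the package namespace).

# Toolmaking chain: string from two fibre bunches, stone tool from two
# refined stones, handaxe from bough + string + stone tool; the handaxe
# plays the role of the craftable "log".
fixture_handaxe_tree <- function() {
  items <- data.frame(
    id = c("bough", "fibres", "rstone", "stonetool", "string", "handaxe"),
    kind = c("base", "base", "base", "intermediate", "intermediate", "log"),
    name = c("bough", "bunch of fibres", "refined stone", "stone tool",
             "string", "handaxe"),
    stringsAsFactors = FALSE)
  recipes <- list(
    string = c("fibres", "fibres"),
    stonetool = c("rstone", "rstone"),
    handaxe = c("bough", "stonetool", "string"))
  new_techtree(items, recipes, base_ids = c("bough", "fibres", "rstone"),
               basic_log_ids = "handaxe",
               params = tree_gen_params(n_base = 3, n_intermediate = 2,
                                        n_logs = 1,
                                        min_basic_log_closure = 3))
}

# Two-step chain a <- (b1, b1), b <- (a, a).
fixture_chain_tree <- function() {
  items <- data.frame(id = c("b1", "a", "b"),
                      kind = c("base", "intermediate", "log"),
                      name = c("b1", "a", "b"), stringsAsFactors = FALSE)
  recipes <- list(a = c("b1", "b1"), b = c("a", "a"))
  new_techtree(items, recipes, base_ids = "b1", basic_log_ids = "b",
               params = tree_gen_params(n_base = 1, n_intermediate = 1,
                                        n_logs = 1,
                                        min_basic_log_closure = 2))
}

# Every single-base combination is a recipe: guaranteed early successes.
fixture_generous_tree <- function() {
  base <- c("b1", "b2", "b3")
  ints <- c("i1", "i2", "i3")
  items <- data.frame(id = c(base, ints, "lg"),
                      kind = c(rep("base", 3), rep("intermediate", 3),
                               "log"),
                      name = c(base, ints, "lg"), stringsAsFactors = FALSE)
  recipes <- list(i1 = "b1", i2 = "b2", i3 = "b3",
                  lg = c("i1", "i2", "i3"))
  new_techtree(items, recipes, base_ids = base, basic_log_ids = "lg",
               params = tree_gen_params(n_base = 3, n_intermediate = 3,
                                        n_logs = 1,
                                        min_basic_log_closure = 4))
}

# A tree with no recipes at all: three base resources only.
fixture_barren_tree <- function() {
  base <- c("b1", "b2", "b3", "b4", "b5", "b6")
  items <- data.frame(id = base, kind = rep("base", 6), name = base,
                      stringsAsFactors = FALSE)
  new_techtree(items, list(), base_ids = base, basic_log_ids = character(0),
               params = tree_gen_params(n_base = 6, n_intermediate = 0,
                                        n_logs = 0, n_basic_logs = 0,
                                        min_basic_log_closure = 1))
}

# Small generated tree used by randomized property tests.
small_tree <- function(seed) {
  generate_tree(tree_gen_params(n_base = 4, n_intermediate = 8, n_logs = 6,
                                n_basic_logs = 2,
                                min_basic_log_closure = 4, seed = seed))
}
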