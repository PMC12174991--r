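# Space-group generator table (standard settings, groups 1-230).
# Each entry: generator operations as xyz triplets; the full group is
# the closure under composition modulo lattice translations.
# Reference data from the standard crystallographic tables.
.sg_table <- list(
  list(number = 1L, hm = "P 1", nops = 1L, gens = c()),
  list(number = 2L, hm = "P -1", nops = 2L, gens = c("-x,-y,-z")),
  list(number = 3L, hm = "P 1 2 1", nops = 2L, gens = c("-x,y,-z")),
  list(number = 4L, hm = "P 1 21 1", nops = 2L, gens = c("-x,y+1/2,-z")),
  list(number = 5L, hm = "C 1 2 1", nops = 4L, gens = c("-x,y,-z", "x+1/2,y+1/2,z")),
  list(number = 6L, hm = "P 1 m 1", nops = 2L, gens = c("x,-y,z")),
  list(number = 7L, hm = "P 1 c 1", nops = 2L, gens = c("x,-y,z+1/2")),
  list(number = 8L, hm = "C 1 m 1", nops = 4L, gens = c("x,-y,z", "x+1/2,y+1/2,z")),
  list(number = 9L, hm = "C 1 c 1", nops = 4L, gens = c("x,-y,z+1/2", "x+1/2,y+1/2,z")),
  list(number = 10L, hm = "P 1 2/m 1", nops = 4L, gens = c("-x,y,-z", "-x,-y,-z")),
  list(number = 11L, hm = "P 1 21/m 1", nops = 4L, gens = c("-x,y+1/2,-z", "-x,-y,-z")),
  list(number = 12L, hm = "C 1 2/m 1", nops = 8L, gens = c("-x,y,-z", "-x,-y,-z", "x+1/2,y+1/2,z")),
  list(number = 13L, hm = "P 1 2/c 1", nops = 4L, gens = c("-x,y,-z+1/2", "-x,-y,-z")),
  list(number = 14L, hm = "P 1 21/c 1", nops = 4L, gens = c("-x,y+1/2,-z+1/2", "-x,-y,-z")),
  list(number = 15L, hm = "C 1 2/c 1", nops = 8L, gens = c("-x,y,-z+1/2", "-x,-y,-z", "x+1/2,y+1/2,z")),
  list(number = 16L, hm = "P 2 2 2", nops = 4L, gens = c("-x,-y,z", "x,-y,-z")),
  list(number = 17L, hm = "P 2 2 21", nops = 4L, gens = c("-x,-y,z+1/2", "x,-y,-z")),
  list(number = 18L, hm = "P 21 21 2", nops = 4L, gens = c("-x,-y,z", "x+1/2,-y+1/2,-z")),
  list(number = 19L, hm = "P 21 21 21", nops = 4L, gens = c("-x+1/2,-y,z+1/2", "x+1/2,-y+1/2,-z")),
  list(number = 20L, hm = "C 2 2 21", nops = 8L, gens = c("-x,-y,z+1/2", "x,-y,-z", "x+1/2,y+1/2,z")),
  list(number = 21L, hm = "C 2 2 2", nops = 8L, gens = c("-x,-y,z", "x,-y,-z", "x+1/2,y+1/2,z")),
  list(number = 22L, hm = "F 2 2 2", nops = 16L, gens = c("-x,-y,z", "x,-y,-z", "x,y+1/2,z+1/2", "x+1/2,y,z+1/2")),
  list(number = 23L, hm = "I 2 2 2", nops = 8L, gens = c("-x,-y,z", "x,-y,-z", "x+1/2,y+1/2,z+1/2")),
  list(number = 24L, hm = "I 21 21 21", nops = 8L, gens = c("-x,-y+1/2,z", "x,-y,-z+1/2", "x+1/2,y+1/2,z+1/2")),
  list(number = 25L, hm = "P m m 2", nops = 4L, gens = c("-x,-y,z", "-x,y,z")),
  list(number = 26L, hm = "P m c 21", nops = 4L, gens = c("-x,-y,z+1/2", "-x,y,z")),
  list(number = 27L, hm = "P c c 2", nops = 4L, gens = c("-x,-y,z", "-x,y,z+1/2")),
  list(number = 28L, hm = "P m a 2", nops = 4L, gens = c("-x,-y,z", "-x+1/2,y,z")),
  list(number = 29L, hm = "P c a 21", nops = 4L, gens = c("-x,-y,z+1/2", "-x+1/2,y,z+1/2")),
  list(number = 30L, hm = "P n c 2", nops = 4L, gens = c("-x,-y,z", "-x,y+1/2,z+1/2")),
  list(number = 31L, hm = "P m n 21", nops = 4L, gens = c("-x+1/2,-y,z+1/2", "-x,y,z")),
  list(number = 32L, hm = "P b a 2", nops = 4L, gens = c("-x,-y,z", "-x+1/2,y+1/2,z")),
  list(number = 33L, hm = "P n a 21", nops = 4L, gens = c("-x,-y,z+1/2", "-x+1/2,y+1/2,z+1/2")),
  list(number = 34L, hm = "P n n 2", nops = 4L, gens = c("-x,-y,z", "-x+1/2,y+1/2,z+1/2")),
  list(number = 35L, hm = "C m m 2", nops = 8L, gens = c("-x,-y,z", "-x,y,z", "x+1/2,y+1/2,z")),
  list(number = 36L, hm = "C m c 21", nops = 8L, gens = c("-x,-y,z+1/2", "-x,y,z", "x+1/2,y+1/2,z")),
  list(number = 37L, hm = "C c c 2", nops = 8L, gens = c("-x,-y,z", "-x,y,z+1/2", "x+1/2,y+1/2,z")),
  list(number = 38L, hm = "A m m 2", nops = 8L, gens = c("-x,-y,z", "-x,y,z", "x,y+1/2,z+1/2")),
  list(number = 39L, hm = "A b m 2", nops = 8L, gens = c("-x,-y,z", "-x,y+1/2,z", "x,y+1/2,z+1/2")),
  list(number = 40L, hm = "A m a 2", nops = 8L, gens = c("-x,-y,z", "-x+1/2,y,z", "x,y+1/2,z+1/2")),
  list(number = 41L, hm = "A b a 2", nops = 8L, gens = c("-x,-y,z", "-x+1/2,y+1/2,z", "x,y+1/2,z+1/2")),
  list(number = 42L, hm = "F m m 2", nops = 16L, gens = c("-x,-y,z", "-x,y,z", "x,y+1/2,z+1/2", "x+1/2,y,z+1/2")),
  list(number = 43L, hm = "F d d 2", nops = 16L, gens = c("-x,-y,z", "-x+1/4,y+1/4,z+1/4")),
  list(number = 44L, hm = "I m m 2", nops = 8L, gens = c("-x,-y,z", "-x,y,z", "x+1/2,y+1/2,z+1/2")),
  list(number = 45L, hm = "I b a 2", nops = 8L, gens = c("-x,-y,z", "-x,y,z+1/2", "x+1/2,y+1/2,z+1/2")),
  list(number = 46L, hm = "I m a 2", nops = 8L, gens = c("-x,-y,z", "-x+1/2,y,z", "x+1/2,y+1/2,z+1/2")),
  list(number = 47L, hm = "P m m m", nops = 8L, gens = c("-x,-y,z", "x,-y,-z", "-x,-y,-z")),
  list(number = 48L, hm = "P n n n", nops = 8L, gens = c("-x,-y,z", "x,-y,-z", "-x+1/2,-y+1/2,-z+1/2")),
  list(number = 49L, hm = "P c c m", nops = 8L, gens = c("-x,-y,z", "x,-y,-z+1/2", "-x,-y,-z")),
  list(number = 50L, hm = "P b a n", nops = 8L, gens = c("-x,-y,z", "x,-y,-z", "-x+1/2,-y+1/2,-z")),
  list(number = 51L, hm = "P m m a", nops = 8L, gens = c("-x+1/2,-y,z", "x+1/2,-y,-z", "-x,-y,-z")),
  list(number = 52L, hm = "P n n a", nops = 8L, gens = c("-x+1/2,-y,z", "x,-y+1/2,-z+1/2", "-x,-y,-z")),
  list(number = 53L, hm = "P m n a", nops = 8L, gens = c("-x+1/2,-y,z+1/2", "x,-y,-z", "-x,-y,-z")),
  list(number = 54L, hm = "P c c a", nops = 8L, gens = c("-x+1/2,-y,z", "x+1/2,-y,-z+1/2", "-x,-y,-z")),
  list(number = 55L, hm = "P b a m", nops = 8L, gens = c("-x,-y,z", "x+1/2,-y+1/2,-z", "-x,-y,-z")),
  list(number = 56L, hm = "P c c n", nops = 8L, gens = c("-x+1/2,-y+1/2,z", "x+1/2,-y,-z+1/2", "-x,-y,-z")),
  list(number = 57L, hm = "P b c m", nops = 8L, gens = c("-x,-y,z+1/2", "x,-y+1/2,-z", "-x,-y,-z")),
  list(number = 58L, hm = "P n n m", nops = 8L, gens = c("-x,-y,z", "x+1/2,-y+1/2,-z+1/2", "-x,-y,-z")),
  list(number = 59L, hm = "P m m n", nops = 8L, gens = c("-x,-y,z", "x+1/2,-y+1/2,-z", "-x+1/2,-y+1/2,-z")),
  list(number = 60L, hm = "P b c n", nops = 8L, gens = c("-x+1/2,-y+1/2,z+1/2", "x+1/2,-y+1/2,-z", "-x,-y,-z")),
  list(number = 61L, hm = "P b c a", nops = 8L, gens = c("-x+1/2,-y,z+1/2", "x+1/2,-y+1/2,-z", "-x,-y,-z")),
  list(number = 62L, hm = "P n m a", nops = 8L, gens = c("-x+1/2,-y,z+1/2", "x+1/2,-y+1/2,-z+1/2", "-x,-y,-z")),
  list(number = 63L, hm = "C m c m", nops = 16L, gens = c("-x,-y,z+1/2", "x,-y,-z", "-x,-y,-z", "x+1/2,y+1/2,z")),
  list(number = 64L, hm = "C m c a", nops = 16L, gens = c("-x+1/2,-y,z+1/2", "x,-y,-z", "-x,-y,-z", "x+1/2,y+1/2,z")),
  list(number = 65L, hm = "C m m m", nops = 16L, gens = c("-x,-y,z", "x,-y,-z", "-x,-y,-z", "x+1/2,y+1/2,z")),
  list(number = 66L, hm = "C c c m", nops = 16L, gens = c("-x,-y,z", "x,-y,-z+1/2", "-x,-y,-z", "x+1/2,y+1/2,z")),
  list(number = 67L, hm = "C m m a", nops = 16L, gens = c("-x+1/2,-y,z", "x,-y,-z", "-x,-y,-z", "x+1/2,y+1/2,z")),
  list(number = 68L, hm = "C c c a", nops = 16L, gens = c("-x,-y,z", "x,-y,-z", "-x+1/2,-y,-z+1/2", "x+1/2,y+1/2,z")),
  list(number = 69L, hm = "F m m m", nops = 32L, gens = c("-x,-y,z", "x,-y,-z", "-x,-y,-z", "x,y+1/2,z+1/2", "x+1/2,y,z+1/2")),
  list(number = 70L, hm = "F d d d", nops = 32L, gens = c("-x,-y,z", "x,-y,-z", "-x+1/4,-y+1/4,-z+1/4")),
  list(number = 71L, hm = "I m m m", nops = 16L, gens = c("-x,-y,z", "x,-y,-z", "-x,-y,-z", "x+1/2,y+1/2,z+1/2")),
  list(number = 72L, hm = "I b a m", nops = 16L, gens = c("-x,-y,z", "x,-y,-z+1/2", "-x,-y,-z", "x+1/2,y+1/2,z+1/2")),
  list(number = 73L, hm = "I b c a", nops = 16L, gens = c("-x,-y+1/2,z", "x,-y,-z+1/2", "-x,-y,-z", "x+1/2,y+1/2,z+1/2")),
  list(number = 74L, hm = "I m m a", nops = 16L, gens = c("-x,-y+1/2,z", "x,-y,-z", "-x,-y,-z", "x+1/2,y+1/2,z+1/2")),
  list(number = 75L, hm = "P 4", nops = 4L, gens = c("-y,x,z")),
  list(number = 76L, hm = "P 41", nops = 4L, gens = c("-y,x,z+1/4")),
  list(number = 77L, hm = "P 42", nops = 4L, gens = c("-y,x,z+1/2")),
  list(number = 78L, hm = "P 43", nops = 4L, gens = c("-y,x,z+3/4")),
  list(number = 79L, hm = "I 4", nops = 8L, gens = c("-y,x,z", "x+1/2,y+1/2,z+1/2")),
  list(number = 80L, hm = "I 41", nops = 8L, gens = c("-y,x+1/2,z+1/4", "x+1/2,y+1/2,z+1/2")),
  list(number = 81L, hm = "P -4", nops = 4L, gens = c("y,-x,-z")),
  list(number = 82L, hm = "I -4", nops = 8L, gens = c("y,-x,-z", "x+1/2,y+1/2,z+1/2")),
  list(number = 83L, hm = "P 4/m", nops = 8L, gens = c("-y,x,z", "-x,-y,-z")),
  list(number = 84L, hm = "P 42/m", nops = 8L, gens = c("-y,x,z+1/2", "-x,-y,-z")),
  list(number = 85L, hm = "P 4/n", nops = 8L, gens = c("-y+1/2,x+1/2,z", "-x+1/2,-y+1/2,-z")),
  list(number = 86L, hm = "P 42/n", nops = 8L, gens = c("-y+1/2,x+1/2,z+1/2", "-x+1/2,-y+1/2,-z+1/2")),
  list(number = 87L, hm = "I 4/m", nops = 16L, gens = c("-y,x,z", "-x,-y,-z", "x+1/2,y+1/2,z+1/2")),
  list(number = 88L, hm = "I 41/a", nops = 16L, gens = c("-y,x+1/2,z+1/4", "-x,-y+1/2,-z+1/4")),
  list(number = 89L, hm = "P 4 2 2", nops = 8L, gens = c("-y,x,z", "x,-y,-z")),
  list(number = 90L, hm = "P 4 21 2", nops = 8L, gens = c("-y+1/2,x+1/2,z", "x+1/2,-y+1/2,-z")),
  list(number = 91L, hm = "P 41 2 2", nops = 8L, gens = c("-y,x,z+1/4", "x,-y,-z+1/2")),
  list(number = 92L, hm = "P 41 21 2", nops = 8L, gens = c("-y+1/2,x+1/2,z+1/4", "x+1/2,-y+1/2,-z+3/4")),
  list(number = 93L, hm = "P 42 2 2", nops = 8L, gens = c("-y,x,z+1/2", "x,-y,-z")),
  list(number = 94L, hm = "P 42 21 2", nops = 8L, gens = c("-y+1/2,x+1/2,z+1/2", "x+1/2,-y+1/2,-z+1/2")),
  list(number = 95L, hm = "P 43 2 2", nops = 8L, gens = c("-y,x,z+3/4", "x,-y,-z+1/2")),
  list(number = 96L, hm = "P 43 21 2", nops = 8L, gens = c("-y+1/2,x+1/2,z+3/4", "x+1/2,-y+1/2,-z+1/4")),
  list(number = 97L, hm = "I 4 2 2", nops = 16L, gens = c("-y,x,z", "x,-y,-z", "x+1/2,y+1/2,z+1/2")),
  list(number = 98L, hm = "I 41 2 2", nops = 16L, gens = c("-y,x+1/2,z+1/4", "x,-y+1/2,-z+1/4", "x+1/2,y+1/2,z+1/2")),
  list(number = 99L, hm = "P 4 m m", nops = 8L, gens = c("-y,x,z", "-x,y,z")),
  list(number = 100L, hm = "P 4 b m", nops = 8L, gens = c("-y,x,z", "-x+1/2,y+1/2,z")),
  list(number = 101L, hm = "P 42 c m", nops = 8L, gens = c("-y,x,z+1/2", "-x,y,z+1/2")),
  list(number = 102L, hm = "P 42 n m", nops = 8L, gens = c("-y+1/2,x+1/2,z+1/2", "-x+1/2,y+1/2,z+1/2")),
  list(number = 103L, hm = "P 4 c c", nops = 8L, gens = c("-y,x,z", "-x,y,z+1/2")),
  list(number = 104L, hm = "P 4 n c", nops = 8L, gens = c("-y,x,z", "-x+1/2,y+1/2,z+1/2")),
  list(number = 105L, hm = "P 42 m c", nops = 8L, gens = c("-y,x,z+1/2", "-x,y,z")),
  list(number = 106L, hm = "P 42 b c", nops = 8L, gens = c("-y,x,z+1/2", "-x+1/2,y+1/2,z")),
  list(number = 107L, hm = "I 4 m m", nops = 16L, gens = c("-y,x,z", "-x,y,z", "x+1/2,y+1/2,z+1/2")),
  list(number = 108L, hm = "I 4 c m", nops = 16L, gens = c("-y,x,z", "-x,y,z+1/2", "x+1/2,y+1/2,z+1/2")),
  list(number = 109L, hm = "I 41 m d", nops = 16L, gens = c("-y,x+1/2,z+1/4", "-x,y,z")),
  list(number = 110L, hm = "I 41 c d", nops = 16L, gens = c("-y,x+1/2,z+1/4", "-x,y,z+1/2")),
  list(number = 111L, hm = "P -4 2 m", nops = 8L, gens = c("y,-x,-z", "x,-y,-z")),
  list(number = 112L, hm = "P -4 2 c", nops = 8L, gens = c("y,-x,-z", "x,-y,-z+1/2")),
  list(number = 113L, hm = "P -4 21 m", nops = 8L, gens = c("y,-x,-z", "x+1/2,-y+1/2,-z")),
  list(number = 114L, hm = "P -4 21 c", nops = 8L, gens = c("y,-x,-z", "x+1/2,-y+1/2,-z+1/2")),
  list(number = 115L, hm = "P -4 m 2", nops = 8L, gens = c("y,-x,-z", "-x,y,z")),
  list(number = 116L, hm = "P -4 c 2", nops = 8L, gens = c("y,-x,-z", "-x,y,z+1/2")),
  list(number = 117L, hm = "P -4 b 2", nops = 8L, gens = c("y,-x,-z", "-x+1/2,y+1/2,z")),
  list(number = 118L, hm = "P -4 n 2", nops = 8L, gens = c("y,-x,-z", "-x+1/2,y+1/2,z+1/2")),
  list(number = 119L, hm = "I -4 m 2", nops = 16L, gens = c("y,-x,-z", "-x,y,z", "x+1/2,y+1/2,z+1/2")),
  list(number = 120L, hm = "I -4 c 2", nops = 16L, gens = c("y,-x,-z", "-x,y,z+1/2", "x+1/2,y+1/2,z+1/2")),
  list(number = 121L, hm = "I -4 2 m", nops = 16L, gens = c("y,-x,-z", "x,-y,-z", "x+1/2,y+1/2,z+1/2")),
  list(number = 122L, hm = "I -4 2 d", nops = 16L, gens = c("y,-x,-z", "x,-y+1/2,-z+1/4")),
  list(number = 123L, hm = "P 4/m m m", nops = 16L, gens = c("-y,x,z", "x,-y,-z", "-x,-y,-z")),
  list(number = 124L, hm = "P 4/m c c", nops = 16L, gens = c("-y,x,z", "x,-y,-z+1/2", "-x,-y,-z")),
  list(number = 125L, hm = "P 4/n b m", nops = 16L, gens = c("-y,x,z", "x,-y,-z", "-x+1/2,-y+1/2,-z")),
  list(number = 126L, hm = "P 4/n n c", nops = 16L, gens = c("-y,x,z", "x,-y,-z", "-x+1/2,-y+1/2,-z+1/2")),
  list(number = 127L, hm = "P 4/m b m", nops = 16L, gens = c("-y,x,z", "x+1/2,-y+1/2,-z", "-x,-y,-z")),
  list(number = 128L, hm = "P 4/m n c", nops = 16L, gens = c("-y,x,z", "x+1/2,-y+1/2,-z+1/2", "-x,-y,-z")),
  list(number = 129L, hm = "P 4/n m m", nops = 16L, gens = c("-y+1/2,x+1/2,z", "x+1/2,-y+1/2,-z", "-x+1/2,-y+1/2,-z")),
  list(number = 130L, hm = "P 4/n c c", nops = 16L, gens = c("-y+1/2,x+1/2,z", "x+1/2,-y+1/2,-z+1/2", "-x+1/2,-y+1/2,-z")),
  list(number = 131L, hm = "P 42/m m c", nops = 16L, gens = c("-y,x,z+1/2", "x,-y,-z", "-x,-y,-z")),
  list(number = 132L, hm = "P 42/m c m", nops = 16L, gens = c("-y,x,z+1/2", "x,-y,-z+1/2", "-x,-y,-z")),
  list(number = 133L, hm = "P 42/n b c", nops = 16L, gens = c("-y+1/2,x+1/2,z+1/2", "x,-y,-z+1/2", "-x+1/2,-y+1/2,-z+1/2")),
  list(number = 134L, hm = "P 42/n n m", nops = 16L, gens = c("-y+1/2,x+1/2,z+1/2", "x,-y,-z", "-x+1/2,-y+1/2,-z+1/2")),
  list(number = 135L, hm = "P 42/m b c", nops = 16L, gens = c("-y,x,z+1/2", "x+1/2,-y+1/2,-z", "-x,-y,-z")),
  list(number = 136L, hm = "P 42/m n m", nops = 16L, gens = c("-y+1/2,x+1/2,z+1/2", "x+1/2,-y+1/2,-z+1/2", "-x,-y,-z")),
  list(number = 137L, hm = "P 42/n m c", nops = 16L, gens = c("-y+1/2,x+1/2,z+1/2", "x+1/2,-y+1/2,-z+1/2", "-x+1/2,-y+1/2,-z+1/2")),
  list(number = 138L, hm = "P 42/n c m", nops = 16L, gens = c("-y+1/2,x+1/2,z+1/2", "x+1/2,-y+1/2,-z", "-x+1/2,-y+1/2,-z+1/2")),
  list(number = 139L, hm = "I 4/m m m", nops = 32L, gens = c("-y,x,z", "x,-y,-z", "-x,-y,-z", "x+1/2,y+1/2,z+1/2")),
  list(number = 140L, hm = "I 4/m c m", nops = 32L, gens = c("-y,x,z", "x,-y,-z+1/2", "-x,-y,-z", "x+1/2,y+1/2,z+1/2")),
  list(number = 141L, hm = "I 41/a m d", nops = 32L, gens = c("-y,x+1/2,z+1/4", "x,-y+1/2,-z+1/4", "-x,-y+1/2,-z+1/4")),
  list(number = 142L, hm = "I 41/a c d", nops = 32L, gens = c("-y,x+1/2,z+1/4", "x+1/2,-y,-z+1/4", "-x,-y+1/2,-z+1/4")),
  list(number = 143L, hm = "P 3", nops = 3L, gens = c("-y,x-y,z")),
  list(number = 144L, hm = "P 31", nops = 3L, gens = c("-y,x-y,z+1/3")),
  list(number = 145L, hm = "P 32", nops = 3L, gens = c("-y,x-y,z+2/3")),
  list(number = 146L, hm = "R 3", nops = 9L, gens = c("-y,x-y,z", "x+2/3,y+1/3,z+1/3")),
  list(number = 147L, hm = "P -3", nops = 6L, gens = c("-y,x-y,z", "-x,-y,-z")),
  list(number = 148L, hm = "R -3", nops = 18L, gens = c("-y,x-y,z", "-x,-y,-z", "x+2/3,y+1/3,z+1/3")),
  list(number = 149L, hm = "P 3 1 2", nops = 6L, gens = c("-y,x-y,z", "-y,-x,-z")),
  list(number = 150L, hm = "P 3 2 1", nops = 6L, gens = c("-y,x-y,z", "y,x,-z")),
  list(number = 151L, hm = "P 31 1 2", nops = 6L, gens = c("-y,x-y,z+1/3", "-y,-x,-z+2/3")),
  list(number = 152L, hm = "P 31 2 1", nops = 6L, gens = c("-y,x-y,z+1/3", "y,x,-z")),
  list(number = 153L, hm = "P 32 1 2", nops = 6L, gens = c("-y,x-y,z+2/3", "-y,-x,-z+1/3")),
  list(number = 154L, hm = "P 32 2 1", nops = 6L, gens = c("-y,x-y,z+2/3", "y,x,-z")),
  list(number = 155L, hm = "R 3 2", nops = 18L, gens = c("-y,x-y,z", "y,x,-z", "x+2/3,y+1/3,z+1/3")),
  list(number = 156L, hm = "P 3 m 1", nops = 6L, gens = c("-y,x-y,z", "-y,-x,z")),
  list(number = 157L, hm = "P 3 1 m", nops = 6L, gens = c("-y,x-y,z", "y,x,z")),
  list(number = 158L, hm = "P 3 c 1", nops = 6L, gens = c("-y,x-y,z", "-y,-x,z+1/2")),
  list(number = 159L, hm = "P 3 1 c", nops = 6L, gens = c("-y,x-y,z", "y,x,z+1/2")),
  list(number = 160L, hm = "R 3 m", nops = 18L, gens = c("-y,x-y,z", "-y,-x,z", "x+2/3,y+1/3,z+1/3")),
  list(number = 161L, hm = "R 3 c", nops = 18L, gens = c("-y,x-y,z", "-y,-x,z+1/2", "x+2/3,y+1/3,z+1/3")),
  list(number = 162L, hm = "P -3 1 m", nops = 12L, gens = c("-y,x-y,z", "-y,-x,-z", "-x,-y,-z")),
  list(number = 163L, hm = "P -3 1 c", nops = 12L, gens = c("-y,x-y,z", "-y,-x,-z+1/2", "-x,-y,-z")),
  list(number = 164L, hm = "P -3 m 1", nops = 12L, gens = c("-y,x-y,z", "y,x,-z", "-x,-y,-z")),
  list(number = 165L, hm = "P -3 c 1", nops = 12L, gens = c("-y,x-y,z", "y,x,-z+1/2", "-x,-y,-z")),
  list(number = 166L, hm = "R -3 m", nops = 36L, gens = c("-y,x-y,z", "y,x,-z", "-x,-y,-z", "x+2/3,y+1/3,z+1/3")),
  list(number = 167L, hm = "R -3 c", nops = 36L, gens = c("-y,x-y,z", "y,x,-z+1/2", "-x,-y,-z", "x+2/3,y+1/3,z+1/3")),
  list(number = 168L, hm = "P 6", nops = 6L, gens = c("x-y,x,z")),
  list(number = 169L, hm = "P 61", nops = 6L, gens = c("x-y,x,z+1/6")),
  list(number = 170L, hm = "P 65", nops = 6L, gens = c("x-y,x,z+5/6")),
  list(number = 171L, hm = "P 62", nops = 6L, gens = c("x-y,x,z+1/3")),
  list(number = 172L, hm = "P 64", nops = 6L, gens = c("x-y,x,z+2/3")),
  list(number = 173L, hm = "P 63", nops = 6L, gens = c("x-y,x,z+1/2")),
  list(number = 174L, hm = "P -6", nops = 6L, gens = c("-x+y,-x,-z")),
  list(number = 175L, hm = "P 6/m", nops = 12L, gens = c("x-y,x,z", "-x,-y,-z")),
  list(number = 176L, hm = "P 63/m", nops = 12L, gens = c("x-y,x,z+1/2", "-x,-y,-z")),
  list(number = 177L, hm = "P 6 2 2", nops = 12L, gens = c("x-y,x,z", "-y,-x,-z")),
  list(number = 178L, hm = "P 61 2 2", nops = 12L, gens = c("x-y,x,z+1/6", "-y,-x,-z+5/6")),
  list(number = 179L, hm = "P 65 2 2", nops = 12L, gens = c("x-y,x,z+5/6", "-y,-x,-z+1/6")),
  list(number = 180L, hm = "P 62 2 2", nops = 12L, gens = c("x-y,x,z+1/3", "-y,-x,-z+2/3")),
  list(number = 181L, hm = "P 64 2 2", nops = 12L, gens = c("x-y,x,z+2/3", "-y,-x,-z+1/3")),
  list(number = 182L, hm = "P 63 2 2", nops = 12L, gens = c("x-y,x,z+1/2", "-y,-x,-z+1/2")),
  list(number = 183L, hm = "P 6 m m", nops = 12L, gens = c("x-y,x,z", "y,x,z")),
  list(number = 184L, hm = "P 6 c c", nops = 12L, gens = c("x-y,x,z", "y,x,z+1/2")),
  list(number = 185L, hm = "P 63 c m", nops = 12L, gens = c("x-y,x,z+1/2", "y,x,z")),
  list(number = 186L, hm = "P 63 m c", nops = 12L, gens = c("x-y,x,z+1/2", "y,x,z+1/2")),
  list(number = 187L, hm = "P -6 m 2", nops = 12L, gens = c("-x+y,-x,-z", "-y,-x,-z")),
  list(number = 188L, hm = "P -6 c 2", nops = 12L, gens = c("-x+y,-x,-z+1/2", "-y,-x,-z")),
  list(number = 189L, hm = "P -6 2 m", nops = 12L, gens = c("-x+y,-x,-z", "y,x,z")),
  list(number = 190L, hm = "P -6 2 c", nops = 12L, gens = c("-x+y,-x,-z+1/2", "y,x,z+1/2")),
  list(number = 191L, hm = "P 6/m m m", nops = 24L, gens = c("x-y,x,z", "-y,-x,-z", "-x,-y,-z")),
  list(number = 192L, hm = "P 6/m c c", nops = 24L, gens = c("x-y,x,z", "-y,-x,-z+1/2", "-x,-y,-z")),
  list(number = 193L, hm = "P 63/m c m", nops = 24L, gens = c("x-y,x,z+1/2", "-y,-x,-z", "-x,-y,-z")),
  list(number = 194L, hm = "P 63/m m c", nops = 24L, gens = c("x-y,x,z+1/2", "-y,-x,-z+1/2", "-x,-y,-z")),
  list(number = 195L, hm = "P 2 3", nops = 12L, gens = c("-x,-y,z", "x,-y,-z", "z,x,y")),
  list(number = 196L, hm = "F 2 3", nops = 48L, gens = c("-x,-y,z", "x,-y,-z", "z,x,y", "x,y+1/2,z+1/2")),
  list(number = 197L, hm = "I 2 3", nops = 24L, gens = c("-x,-y,z", "x,-y,-z", "z,x,y", "x+1/2,y+1/2,z+1/2")),
  list(number = 198L, hm = "P 21 3", nops = 12L, gens = c("-x+1/2,-y,z+1/2", "x+1/2,-y+1/2,-z", "z,x,y")),
  list(number = 199L, hm = "I 21 3", nops = 24L, gens = c("-x,-y+1/2,z", "x,-y,-z+1/2", "z,x,y")),
  list(number = 200L, hm = "P m -3", nops = 24L, gens = c("-x,-y,z", "x,-y,-z", "z,x,y", "-x,-y,-z")),
  list(number = 201L, hm = "P n -3", nops = 24L, gens = c("-x,-y,z", "x,-y,-z", "z,x,y", "-x+1/2,-y+1/2,-z+1/2")),
  list(number = 202L, hm = "F m -3", nops = 96L, gens = c("-x,-y,z", "x,-y,-z", "z,x,y", "-x,-y,-z", "x,y+1/2,z+1/2")),
  list(number = 203L, hm = "F d -3", nops = 96L, gens = c("-x,-y,z", "x,-y,-z", "z,x,y", "-x+1/4,-y+1/4,-z+1/4")),
  list(number = 204L, hm = "I m -3", nops = 48L, gens = c("-x,-y,z", "x,-y,-z", "z,x,y", "-x,-y,-z", "x+1/2,y+1/2,z+1/2")),
  list(number = 205L, hm = "P a -3", nops = 24L, gens = c("-x+1/2,-y,z+1/2", "x+1/2,-y+1/2,-z", "z,x,y", "-x,-y,-z")),
  list(number = 206L, hm = "I a -3", nops = 48L, gens = c("-x,-y+1/2,z", "x,-y,-z+1/2", "z,x,y", "-x,-y,-z")),
  list(number = 207L, hm = "P 4 3 2", nops = 24L, gens = c("-y,x,z", "x,-y,-z", "z,x,y")),
  list(number = 208L, hm = "P 42 3 2", nops = 24L, gens = c("-y+1/2,x+1/2,z+1/2", "x,-y,-z", "z,x,y")),
  list(number = 209L, hm = "F 4 3 2", nops = 96L, gens = c("-y,x,z", "x,-y,-z", "z,x,y", "x,y+1/2,z+1/2")),
  list(number = 210L, hm = "F 41 3 2", nops = 96L, gens = c("-y+1/4,x+1/4,z+1/4", "x,-y,-z", "z,x,y")),
  list(number = 211L, hm = "I 4 3 2", nops = 48L, gens = c("-y,x,z", "x,-y,-z", "z,x,y", "x+1/2,y+1/2,z+1/2")),
  list(number = 212L, hm = "P 43 3 2", nops = 24L, gens = c("-y+3/4,x+1/4,z+3/4", "x+1/2,-y+1/2,-z", "z,x,y")),
  list(number = 213L, hm = "P 41 3 2", nops = 24L, gens = c("-y+1/4,x+3/4,z+1/4", "x+1/2,-y+1/2,-z", "z,x,y")),
  list(number = 214L, hm = "I 41 3 2", nops = 48L, gens = c("-y+1/4,x+3/4,z+1/4", "x,-y,-z+1/2", "z,x,y")),
  list(number = 215L, hm = "P -4 3 m", nops = 24L, gens = c("y,-x,-z", "x,-y,-z", "z,x,y")),
  list(number = 216L, hm = "F -4 3 m", nops = 96L, gens = c("y,-x,-z", "x,-y,-z", "z,x,y", "x,y+1/2,z+1/2")),
  list(number = 217L, hm = "I -4 3 m", nops = 48L, gens = c("y,-x,-z", "x,-y,-z", "z,x,y", "x+1/2,y+1/2,z+1/2")),
  list(number = 218L, hm = "P -4 3 n", nops = 24L, gens = c("y+1/2,-x+1/2,-z+1/2", "x,-y,-z", "z,x,y")),
  list(number = 219L, hm = "F -4 3 c", nops = 96L, gens = c("y+1/2,-x,-z", "x,-y,-z", "z,x,y")),
  list(number = 220L, hm = "I -4 3 d", nops = 48L, gens = c("y+1/4,-x+3/4,-z+1/4", "x,-y,-z+1/2", "z,x,y")),
  list(number = 221L, hm = "P m -3 m", nops = 48L, gens = c("-y,x,z", "x,-y,-z", "z,x,y", "-x,-y,-z")),
  list(number = 222L, hm = "P n -3 n", nops = 48L, gens = c("-y,x,z", "x,-y,-z", "z,x,y", "-x+1/2,-y+1/2,-z+1/2")),
  list(number = 223L, hm = "P m -3 n", nops = 48L, gens = c("-y+1/2,x+1/2,z+1/2", "x,-y,-z", "z,x,y", "-x,-y,-z")),
  list(number = 224L, hm = "P n -3 m", nops = 48L, gens = c("-y+1/2,x+1/2,z+1/2", "x,-y,-z", "z,x,y", "-x+1/2,-y+1/2,-z+1/2")),
  list(number = 225L, hm = "F m -3 m", nops = 192L, gens = c("-y,x,z", "x,-y,-z", "z,x,y", "-x,-y,-z", "x,y+1/2,z+1/2")),
  list(number = 226L, hm = "F m -3 c", nops = 192L, gens = c("-y+1/2,x,z", "x,-y,-z", "z,x,y", "-x,-y,-z")),
  list(number = 227L, hm = "F d -3 m", nops = 192L, gens = c("-y+1/4,x+1/4,z+1/4", "x,-y,-z", "z,x,y", "-x+1/4,-y+1/4,-z+1/4")),
  list(number = 228L, hm = "F d -3 c", nops = 192L, gens = c("-y+1/4,x+1/4,z+1/4", "x,-y,-z", "z,x,y", "-x+3/4,-y+1/4,-z+1/4")),
  list(number = 229L, hm = "I m -3 m", nops = 96L, gens = c("-y,x,z", "x,-y,-z", "z,x,y", "-x,-y,-z", "x+1/2,y+1/2,z+1/2")),
  list(number = 230L, hm = "I a -3 d", nops = 96L, gens = c("-y+1/4,x+3/4,z+1/4", "x,-y,-z+1/2", "z,x,y", "-x,-y,-z"))
)
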