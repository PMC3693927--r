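# fixture common-English word list (case-insensitive lookup)
a
about
after
again
algorithm
alignment
all
also
an
analysis
and
annotation
any
applied
approach
are
article
available
based
be
been
before
between
biology
both
but
by
can
carefully
case
change
changes
cluster
collection
common
comparison
compute
computed
contains
corpus
count
counted
counting
data
database
databases
dataset
described
detail
details
developed
different
discussion
document
documents
during
each
effect
entries
entry
evaluation
every
example
experiment
experiments
fast
feature
features
field
figure
file
files
final
first
following
for
format
found
fox
free
from
further
gene
genes
genome
genomes
given
global
graph
group
groups
have
here
high
identifier
identifiers
in
information
interface
into
is
it
its
journal
journals
kind
known
large
last
level
levels
list
lists
literature
local
low
main
many
mapping
match
matches
measured
mention
mentions
method
methods
model
models
more
most
name
names
network
networks
new
no
not
noun
novel
number
numbers
of
often
on
once
one
only
onto
open
or
other
our
output
over
paper
papers
part
pattern
patterns
per
performed
pipeline
platform
possible
previous
process
processing
program
programs
protein
proteins
public
quick
rate
rates
read
reads
record
records
reference
references
repeated
report
reports
research
response
result
results
run
runs
same
sample
samples
science
score
scores
search
second
section
sections
sentence
sentences
sequence
sequences
set
sets
several
show
shown
single
small
software
some
species
standard
step
steps
structure
structures
study
such
survey
system
systems
table
tables
term
terms
test
tests
text
texts
than
that
the
their
then
these
this
those
through
time
times
to
tool
tools
total
tree
trees
twice
two
under
unique
usage
use
used
value
values
variant
variants
version
versions
was
we
web
were
which
wide
widget
widgets
with
within
word
words
work
workflow
year
years
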