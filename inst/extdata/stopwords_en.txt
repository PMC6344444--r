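# Bundled English stop-word list, v1.
# Used by the deterministic fallback content-word filter: articles,
# prepositions, conjunctions, pronouns, auxiliaries and common adverbs.
# One lowercase word per line; "#" lines are comments.
a
an
the
all
any
both
each
either
neither
every
few
many
much
more
most
several
some
such
no
nor
not
only
own
same
so
than
too
very
just
and
or
but
if
because
as
until
while
when
where
why
how
what
which
who
whom
whose
that
this
these
those
am
is
are
was
were
be
been
being
have
has
had
having
do
does
did
doing
will
would
shall
should
can
could
may
might
must
ought
i
me
my
mine
myself
we
us
our
ours
ourselves
you
your
yours
yourself
yourselves
he
him
his
himself
she
her
hers
herself
it
its
itself
they
them
their
theirs
themselves
one
ones
of
at
by
for
with
about
against
between
among
into
through
during
before
after
above
below
to
from
up
down
in
out
on
off
over
under
again
further
then
once
here
there
also
however
moreover
therefore
thus
hence
furthermore
nevertheless
nonetheless
meanwhile
otherwise
although
though
whereas
whether
since
within
without
upon
toward
towards
onto
per
via
versus
amid
along
across
around
beyond
besides
despite
except
near
rather
quite
almost
already
always
never
often
sometimes
usually
together
well
still
yet
even
ever
else
perhaps
likely
indeed
instead
respectively
et
al
etc
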