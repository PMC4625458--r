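a
about
above
across
actually
after
afterwards
again
against
all
almost
alone
along
already
also
although
always
am
among
amongst
an
and
another
any
anyhow
anyone
anything
anyway
anywhere
are
aren
around
as
at
back
be
became
because
become
becomes
becoming
been
before
beforehand
behind
being
below
beside
besides
between
beyond
both
bottom
but
by
can
cannot
could
couldn
did
didn
do
does
doesn
doing
don
done
down
during
each
eg
eight
either
else
elsewhere
enough
etc
even
ever
every
everyone
everything
everywhere
except
few
fifteen
fifty
first
five
for
former
formerly
forty
four
from
further
had
hadn
has
hasn
have
haven
having
he
hence
her
here
hereafter
hereby
herein
hereupon
hers
herself
him
himself
his
how
however
hundred
i
ie
if
in
indeed
instead
into
is
isn
it
its
itself
just
last
latter
latterly
least
less
like
ll
made
many
may
me
meanwhile
might
mine
more
moreover
most
mostly
much
must
mustn
my
myself
namely
need
neither
never
nevertheless
next
nine
no
nobody
none
nor
not
nothing
now
nowhere
of
off
often
on
once
one
only
onto
or
other
others
otherwise
our
ours
ourselves
out
over
own
part
per
perhaps
please
put
quite
rather
re
really
same
say
see
seem
seemed
seeming
seems
several
shan
she
should
shouldn
show
side
since
six
sixty
so
some
somehow
someone
something
sometime
sometimes
somewhere
still
such
ten
than
that
the
their
theirs
them
themselves
then
thence
there
thereafter
thereby
therefore
therein
thereupon
these
they
third
this
those
though
three
through
throughout
thru
thus
to
together
too
top
toward
towards
twelve
twenty
two
under
until
up
upon
us
used
using
various
ve
very
via
was
wasn
we
well
were
weren
what
whatever
when
whence
whenever
where
whereafter
whereas
whereby
wherein
whereupon
wherever
whether
which
while
whither
who
whoever
whole
whom
whose
why
will
with
within
without
won
would
wouldn
yet
you
your
yours
yourself
yourselves
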