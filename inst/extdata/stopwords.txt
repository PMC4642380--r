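a
about
after
again
all
also
am
an
and
any
are
as
at
be
because
been
before
but
by
can
cant
could
did
do
does
doesnt
dont
down
for
from
had
has
have
he
her
here
him
his
how
id
if
ill
im
in
into
is
it
its
ive
just
like
me
more
most
my
no
not
now
of
off
on
only
or
other
our
out
over
she
so
some
such
than
that
the
their
them
then
there
these
they
this
those
through
to
too
under
up
very
was
we
were
what
when
where
which
while
who
why
will
with
wont
would
you
your
youre
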