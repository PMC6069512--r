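# one stop word per line; indicator lemmas and negation words are never
# treated as stop words even if listed here (the loader drops them).
a
an
the
and
or
but
if
then
than
that
this
these
those
there
here
is
am
are
was
were
be
been
being
has
have
had
having
do
does
did
done
will
would
shall
should
can
could
may
might
must
of
in
on
at
by
for
with
to
from
as
into
onto
upon
about
over
under
again
also
just
so
such
too
very
own
same
it
its
he
him
his
she
her
hers
they
them
their
we
us
our
you
your
i
me
my
who
whom
which
what
when
where
why
how
all
any
both
each
few
more
most
other
some
only
per
via
either
because
while
during
before
after
between
out
up
down
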