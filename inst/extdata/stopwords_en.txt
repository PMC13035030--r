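a
about
after
all
also
an
and
any
are
as
at
be
been
but
by
can
could
did
do
for
from
had
has
have
he
her
his
i
if
in
into
is
it
its
may
more
no
not
of
on
or
our
she
should
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
to
was
we
were
what
when
which
who
will
with
would
you
your
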